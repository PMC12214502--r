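# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so generators do not
#' perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# "20" -> "20", "-10" -> "m10": threshold tag usable in column names
thr_label <- function(t) {
  gsub("-", "m", format(t, trim = TRUE, scientific = FALSE))
}

# "0.9" -> "p90", 0.01 -> "p01"
pct_label <- function(p) {
  sprintf("p%02d", as.integer(round(p * 100)))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

is_regular <- function(x, tol = 1e-8) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  all(abs(d - d[1L]) < tol * max(abs(d[1L]), 1))
}

# calendar dates (Date) for each timestamp, UTC day boundary
utc_date <- function(time) {
  as.Date(floor(as.numeric(time) / 86400), origin = "1970-01-01")
}

days_in_year <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}
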