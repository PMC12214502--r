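# Extreme-temperature wave detection: maximal runs of consecutive
# extreme days per region and threshold.

#' Detect maximal runs of TRUE in a boolean series
#'
#' Returns every maximal run of consecutive `TRUE` values of length at
#' least `min_length`, in chronological order.  `NA` flags are treated as
#' `FALSE` (a day with a missing measure cannot be certified extreme and
#' breaks a run).
#'
#' @param flags Logical vector over contiguous dates.
#' @param min_length Minimum run length (>= 1); default 2, the shortest
#'   period that qualifies as a wave.
#' @return A data.frame with integer columns `start`, `end`, `length`
#'   (positions into `flags`); zero rows if there is no qualifying run.
#' @export
#' @examples
#' detect_runs(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
detect_runs <- function(flags, min_length = 2L) {
  min_length <- as.integer(min_length)
  if (min_length < 1L) stop("`min_length` must be >= 1", call. = FALSE)
  flags <- as.logical(flags)
  flags[is.na(flags)] <- FALSE
  if (length(flags) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Default wave threshold specifications
#'
#' The twelve wave types: heatwaves above 20, 30, 40 degC and above the
#' 90th, 95th, 99th percentiles; coldsnaps below 10, 0, -10 degC and
#' below the 10th, 5th, 1st percentiles.
#'
#' @param measure Daily measure the thresholds apply to; default
#'   `"t_mean"`, consistent with the absolute-threshold yearly metrics.
#' @return Named list of [threshold_spec()] objects.
#' @export
default_wave_specs <- function(measure = "t_mean") {
  specs <- list()
  for (t in c(20, 30, 40)) {
    specs[[paste0("heat_above_", thr_label(t))]] <-
      threshold_spec(measure, "above", "absolute", t)
  }
  for (p in c(0.90, 0.95, 0.99)) {
    specs[[paste0("heat_above_", pct_label(p))]] <-
      threshold_spec(measure, "above", "percentile", p)
  }
  for (t in c(10, 0, -10)) {
    specs[[paste0("cold_below_", thr_label(t))]] <-
      threshold_spec(measure, "below", "absolute", t)
  }
  for (p in c(0.10, 0.05, 0.01)) {
    specs[[paste0("cold_below_", pct_label(p))]] <-
      threshold_spec(measure, "below", "percentile", p)
  }
  specs
}

#' Build the wave table
#'
#' For every region and threshold specification, finds all maximal runs
#' of at least `min_length` consecutive extreme days and emits one record
#' per run with its start date, end date and length.  Runs are computed
#' over each region's full contiguous daily series, so waves may cross
#' calendar-year boundaries (winter coldsnaps straddle New Year).
#'
#' @param daily A daily measures table with contiguous dates per region.
#' @param thresholds A [percentile_thresholds()] table, required when any
#'   spec is percentile-based.
#' @param specs Named list of [threshold_spec()]; default
#'   [default_wave_specs()].
#' @param min_length Minimum days per wave (default 2).
#' @return A tibble with columns `region_id`, `wave_type`,
#'   `threshold_kind`, `threshold_value` (degC for absolute specs, the
#'   probability for percentile specs), `threshold_degc` (the resolved
#'   per-region cutoff), `start_date`, `end_date`, `n_days`.
#' @export
build_wave_table <- function(daily, thresholds = NULL,
                             specs = default_wave_specs(),
                             min_length = 2L) {
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("`specs` must be a named list of threshold_spec", call. = FALSE)
  }
  ids <- sort(unique(daily$region_id))
  out <- list()
  for (id in ids) {
    d <- daily[daily$region_id == id, ]
    d <- d[order(d$date), ]
    if (nrow(d) > 1L && any(diff(as.integer(d$date)) != 1L)) {
      stop("dates not contiguous for region ", id,
           ": runs are undefined across gaps", call. = FALSE)
    }
    for (nm in names(specs)) {
      spec <- specs[[nm]]
      stopifnot(inherits(spec, "threshold_spec"))
      x <- d[[spec$measure]]
      if (is.null(x)) stop("measure ", spec$measure, " not in daily table",
                           call. = FALSE)
      cut <- resolve_threshold(spec, thresholds, id)
      flags <- if (spec$direction == "above") x > cut else x < cut
      runs <- detect_runs(flags, min_length)
      if (nrow(runs) == 0L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        region_id = id,
        wave_type = nm,
        threshold_kind = spec$kind,
        threshold_value = spec$value,
        threshold_degc = cut,
        start_date = d$date[runs$start],
        end_date = d$date[runs$end],
        n_days = runs$length
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(region_id = character(0), wave_type = character(0),
                          threshold_kind = character(0),
                          threshold_value = numeric(0),
                          threshold_degc = numeric(0),
                          start_date = as.Date(character(0)),
                          end_date = as.Date(character(0)),
                          n_days = integer(0)))
  }
  do.call(rbind, out)
}
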