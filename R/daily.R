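# Daily region-level measures: collapse hourly regional series to daily
# minimum / maximum / mean per calendar (UTC) date.

#' Daily summary of one region-date's hourly values
#'
#' The daily minimum, maximum and mean are the lowest, highest and average
#' of the hourly values available for the region on the calendar date.
#' Missing hours are excluded; a date with no non-missing hour yields all
#' three measures missing.
#'
#' @param x Numeric vector of hourly values (up to 24).
#' @return Named numeric vector `c(min, max, mean)`.
#' @export
#' @examples
#' hourly_to_daily(0:23)  # c(0, 23, 11.5)
hourly_to_daily <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(c(min = NA_real_, max = NA_real_, mean = NA_real_))
  }
  c(min = min(x), max = max(x), mean = mean(x))
}

#' Build the daily measures table
#'
#' Computes, for every region and calendar date, the daily minimum,
#' maximum and mean of the regional hourly series.  The aggregation order
#' is: equal-weight (or population-weighted) zonal mean of the hourly
#' field first, then min/max/mean over the (up to 24) regional hourly
#' values of the UTC calendar date.
#'
#' Population-weighted columns (`t_min_pw`, `t_max_pw`, `t_mean_pw`) are
#' produced only when `population` is supplied, and only for dates in
#' years not earlier than the first population epoch; each year is
#' weighted with the epoch chosen by [select_population_epoch()].  An
#' optional thermal-comfort index grid (`utci`), typically at a coarser
#' resolution, is processed identically on its own cell assignment and
#' contributes `utci_min`, `utci_max`, `utci_mean` columns.
#'
#' @param grid An [hourly_grid()] with the primary temperature field.
#' @param regions A [region_set()].
#' @param population Optional [population_grid()].
#' @param utci Optional [hourly_grid()] with a comfort-index field.
#' @param date_range Optional length-2 vector (`Date` or `"YYYY-MM-DD"`)
#'   restricting the output; must lie within the grid coverage.
#' @return A tibble with columns `region_id`, `date`, `t_min`, `t_max`,
#'   `t_mean` and the optional `_pw` / `utci_` columns, one row per
#'   (region, date), sorted by region then date.
#' @export
build_daily_table <- function(grid, regions, population = NULL, utci = NULL,
                              date_range = NULL) {
  stopifnot(inherits(grid, "hourly_grid"), inherits(regions, "region_set"))
  all_dates <- utc_date(grid$time)
  if (is.null(date_range)) {
    date_range <- range(all_dates)
  } else {
    date_range <- as.Date(date_range)
    if (date_range[1L] < min(all_dates) || date_range[2L] > max(all_dates)) {
      stop("date_range outside grid coverage (",
           min(all_dates), " .. ", max(all_dates), ")", call. = FALSE)
    }
  }
  keep <- all_dates >= date_range[1L] & all_dates <= date_range[2L]

  assignment <- assign_cells(grid, regions)
  ids <- regions$region_id
  vmat <- flatten_grid(grid)[keep, , drop = FALSE]
  dates <- all_dates[keep]

  W <- equal_weight_matrix(assignment, ids)
  eq <- daily_stats(vmat %*% W, dates)

  out <- tibble::tibble(
    region_id = rep(ids, each = nrow(eq$min)),
    date = rep(eq$dates, times = length(ids)),
    t_min = as.vector(eq$min), t_max = as.vector(eq$max),
    t_mean = as.vector(eq$mean)
  )

  if (!is.null(population)) {
    pw <- pop_weighted_hourly(vmat, dates, assignment, ids, grid, population)
    st <- daily_stats(pw, dates)
    out$t_min_pw <- as.vector(st$min)
    out$t_max_pw <- as.vector(st$max)
    out$t_mean_pw <- as.vector(st$mean)
  }

  if (!is.null(utci)) {
    u <- build_daily_table(utci, regions, date_range = date_range)
    names(u)[match(c("t_min", "t_max", "t_mean"), names(u))] <-
      c("utci_min", "utci_max", "utci_mean")
    out <- merge(out, u, by = c("region_id", "date"), all.x = TRUE,
                 sort = FALSE)
    out <- tibble::as_tibble(out)
  }

  out[order(out$region_id, out$date), ]
}

# grid values as an (n_time x n_cell) matrix with masked columns zeroed,
# so matrix products with zero weights stay finite
flatten_grid <- function(grid) {
  ntime <- length(grid$time)
  vmat <- grid$values
  dim(vmat) <- c(ntime, length(grid$lat) * length(grid$lon))
  masked <- which(as.vector(grid$mask))
  if (length(masked)) vmat[, masked] <- 0
  vmat
}

# n_cell x n_region equal-weight matrix; all-NA column for empty regions
equal_weight_matrix <- function(assignment, ids) {
  ncell <- prod(assignment$dim)
  W <- matrix(0, ncell, length(ids))
  for (r in seq_along(ids)) {
    cells <- assignment$cells[[ids[r]]]
    if (length(cells) == 0L) W[, r] <- NA_real_
    else W[cells, r] <- 1 / length(cells)
  }
  W
}

# population-weighted regional hourly series, epoch chosen per year
pop_weighted_hourly <- function(vmat, dates, assignment, ids, grid,
                                population) {
  years <- as.integer(format(dates, "%Y"))
  pw <- matrix(NA_real_, nrow(vmat), length(ids))
  epoch_for_year <- vapply(sort(unique(years)), function(y) {
    select_population_epoch(y, population$epochs)
  }, integer(1))
  names(epoch_for_year) <- sort(unique(years))
  for (e in unique(epoch_for_year[!is.na(epoch_for_year)])) {
    pop_slice <- align_population(population, grid, e)
    Wp <- matrix(0, prod(assignment$dim), length(ids))
    for (r in seq_along(ids)) {
      cells <- assignment$cells[[ids[r]]]
      tot <- sum(pop_slice[cells])
      if (length(cells) == 0L || tot == 0) {
        if (length(cells) > 0L) {
          warning("zero total population weight in region ", ids[r],
                  " for epoch ", e,
                  "; population-weighted measures are missing",
                  call. = FALSE)
        }
        Wp[, r] <- NA_real_
      } else {
        Wp[cells, r] <- pop_slice[cells] / tot
      }
    }
    yrs_e <- as.integer(names(epoch_for_year)[epoch_for_year == e &
                                                !is.na(epoch_for_year)])
    rows <- which(years %in% yrs_e)
    pw[rows, ] <- vmat[rows, , drop = FALSE] %*% Wp
  }
  pw
}

# collapse an (n_time x n_region) hourly matrix to daily min/max/mean
daily_stats <- function(reg_hourly, dates) {
  udates <- sort(unique(dates))
  day_idx <- match(dates, udates)
  nreg <- ncol(reg_hourly)
  counts <- tabulate(day_idx, length(udates))
  if (all(counts == 24L) && !is.unsorted(day_idx)) {
    # fast path: complete days in order -> reshape to 24 x n_days blocks
    ndays <- length(udates)
    mn <- mx <- mean_ <- matrix(NA_real_, ndays, nreg)
    for (r in seq_len(nreg)) {
      m <- matrix(reg_hourly[, r], nrow = 24L)
      rows <- asplit(m, 1L)
      mn[, r] <- do.call(pmin, rows)
      mx[, r] <- do.call(pmax, rows)
      mean_[, r] <- .colMeans(m, 24L, ndays)
    }
  } else {
    groups <- split(seq_along(day_idx), day_idx)
    ndays <- length(udates)
    mn <- mx <- mean_ <- matrix(NA_real_, ndays, nreg)
    for (r in seq_len(nreg)) {
      col <- reg_hourly[, r]
      s <- vapply(groups, function(ix) hourly_to_daily(col[ix]), numeric(3))
      mn[as.integer(names(groups)), r] <- s[1L, ]
      mx[as.integer(names(groups)), r] <- s[2L, ]
      mean_[as.integer(names(groups)), r] <- s[3L, ]
    }
  }
  list(dates = udates, min = mn, max = mx, mean = mean_)
}
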