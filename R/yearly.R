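# Yearly extreme-temperature metrics: threshold day counts, expected
# exceedance fractions, degree days, and reference-period percentile
# thresholds.

#' Default absolute threshold sets and percentiles
#'
#' Heat thresholds apply to days *above*, cold thresholds to days *below*
#' (both strict); percentiles define the local (region-relative) metrics.
#' @name metric_defaults
#' @export
HEAT_THRESHOLDS <- c(20, 25, 30, 35, 40, 45)
#' @rdname metric_defaults
#' @export
COLD_THRESHOLDS <- c(-20, -15, -10, -5, 0, 5)
#' @rdname metric_defaults
#' @export
UPPER_PERCENTILES <- c(0.90, 0.95, 0.99)
#' @rdname metric_defaults
#' @export
LOWER_PERCENTILES <- c(0.01, 0.05, 0.10)
#' @rdname metric_defaults
#' @export
TROPICAL_NIGHT_TMIN <- 20
#' @rdname metric_defaults
#' @export
POLAR_DAY_TMAX <- 10
#' @rdname metric_defaults
#' @export
CDD_BASE <- 24
#' @rdname metric_defaults
#' @export
HDD_BASE <- 20

#' Threshold specification
#'
#' Describes one extreme-day criterion: which daily measure it applies
#' to, the direction of the exceedance, and either a fixed temperature
#' (`kind = "absolute"`, the same cutoff for every region) or a
#' reference-period percentile (`kind = "percentile"`, a per-region
#' cutoff looked up in a [percentile_thresholds()] table).  All
#' comparisons are strict.
#'
#' @param measure Daily measure column name (e.g. `"t_mean"`, `"t_max"`).
#' @param direction `"above"` or `"below"`.
#' @param kind `"absolute"` or `"percentile"`.
#' @param value Temperature in degC (absolute) or a probability in (0, 1)
#'   (percentile).
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(measure = "t_mean",
                           direction = c("above", "below"),
                           kind = c("absolute", "percentile"),
                           value) {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  stopifnot_scalar_number(value, "value")
  if (kind == "percentile" && (value <= 0 || value >= 1)) {
    stop("percentile `value` must be in (0, 1)", call. = FALSE)
  }
  if (kind == "absolute" && !is.finite(value)) {
    stop("absolute `value` must be finite", call. = FALSE)
  }
  structure(list(measure = measure, direction = direction, kind = kind,
                 value = value),
            class = "threshold_spec")
}

#' Per-region percentile thresholds from a reference period
#'
#' Computes, for each region, the empirical quantile of a daily measure
#' over a historical reference window (all calendar days pooled).  These
#' are the per-region cutoffs `t(p, j)` behind every local (relative)
#' metric.  Quantiles use linear interpolation between order statistics
#' (R's default type 7).
#'
#' @param daily A daily measures table (see [build_daily_table()]).
#' @param percentiles Probabilities in (0, 1); default the six used by
#'   the yearly metrics.
#' @param measure Daily measure column; default `"t_mean"`.
#' @param reference_years Length-2 integer vector, first and last year of
#'   the reference window (inclusive); default `c(1950, 1990)`.
#' @return A tibble of class `percentile_table` with columns `region_id`,
#'   `p`, `value`, carrying the reference window and measure as
#'   attributes.
#' @export
percentile_thresholds <- function(daily,
                                  percentiles = c(LOWER_PERCENTILES,
                                                  UPPER_PERCENTILES),
                                  measure = "t_mean",
                                  reference_years = c(1950, 1990)) {
  stopifnot(measure %in% names(daily))
  if (any(percentiles <= 0 | percentiles >= 1)) {
    stop("percentiles must be in (0, 1)", call. = FALSE)
  }
  percentiles <- sort(percentiles)
  yr <- as.integer(format(daily$date, "%Y"))
  ref <- daily[yr >= reference_years[1L] & yr <= reference_years[2L], ]
  ids <- sort(unique(daily$region_id))
  have <- vapply(ids, function(id) {
    any(ref$region_id == id & !is.na(ref[[measure]]))
  }, logical(1))
  if (any(!have)) {
    stop("no reference-period data for region(s): ",
         paste(ids[!have], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    x <- ref[[measure]][ref$region_id == id]
    x <- x[!is.na(x)]
    tibble::tibble(region_id = id, p = percentiles,
                   value = unname(stats::quantile(x, percentiles, type = 7)))
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_years") <- as.integer(reference_years)
  attr(out, "measure") <- measure
  class(out) <- c("percentile_table", class(out))
  out
}

# resolve a threshold_spec to a temperature for one region
resolve_threshold <- function(spec, thresholds = NULL, region_id = NULL) {
  if (spec$kind == "absolute") return(spec$value)
  if (is.null(thresholds)) {
    stop("percentile threshold requires a percentile_thresholds() table",
         call. = FALSE)
  }
  hit <- thresholds$region_id == region_id &
    abs(thresholds$p - spec$value) < 1e-9
  if (!any(hit)) {
    stop("no percentile threshold for region ", region_id, " at p = ",
         spec$value, call. = FALSE)
  }
  thresholds$value[hit][1L]
}

#' Count extreme days in a series
#'
#' Number of days on which a daily series strictly exceeds (or falls
#' strictly below) the threshold resolved from `spec`.  Tropical nights
#' are `count_threshold_days` of `t_min` above 20 degC; polar days of
#' `t_max` below 10 degC.
#'
#' @param series Numeric daily values for one region (typically one
#'   calendar year); missing days are not counted.
#' @param spec A [threshold_spec()].
#' @param thresholds A [percentile_thresholds()] table, required for
#'   percentile specs.
#' @param region_id Region identifier, required for percentile specs.
#' @return Integer day count.
#' @export
count_threshold_days <- function(series, spec, thresholds = NULL,
                                 region_id = NULL) {
  stopifnot(inherits(spec, "threshold_spec"))
  t <- resolve_threshold(spec, thresholds, region_id)
  if (spec$direction == "above") sum(series > t, na.rm = TRUE)
  else sum(series < t, na.rm = TRUE)
}

#' Empirical distribution function value
#'
#' Fraction of reference observations less than or equal to `t` --
#' the basis of the expected-days metrics: expected fraction of days
#' below `t` is `F_n(t)`, above is `1 - F_n(t)`.
#'
#' @param reference_series Numeric reference observations (non-empty).
#' @param t Threshold in the series' units.
#' @return Fraction in `[0, 1]`.
#' @export
ecdf_fraction <- function(reference_series, t) {
  reference_series <- reference_series[!is.na(reference_series)]
  if (length(reference_series) == 0L) {
    stop("empty reference series", call. = FALSE)
  }
  stats::ecdf(reference_series)(t)
}

#' Cooling and heating degree days
#'
#' Annual sums of degrees by which a daily temperature summary `m` is
#' above 24 degC (cooling) or below 20 degC (heating), with strict
#' inequalities.  The `standard` variant uses the daily midpoint
#' `m = (t_max + t_min) / 2`, the conventional degree-day summary.  The
#' `as_printed` variant substitutes the half-range
#' `m = (t_max - t_min) / 2`, for literal reproduction of pipelines that
#' define it that way.
#'
#' @param t_max_series,t_min_series Paired daily series of equal length.
#' @param kind `"cooling"` or `"heating"`.
#' @param formula_variant `"standard"` (midpoint, default) or
#'   `"as_printed"` (half-range).
#' @return Degree days in degC (>= 0).
#' @export
degree_days <- function(t_max_series, t_min_series,
                        kind = c("cooling", "heating"),
                        formula_variant = c("standard", "as_printed")) {
  kind <- match.arg(kind)
  formula_variant <- match.arg(formula_variant)
  if (length(t_max_series) != length(t_min_series)) {
    stop("t_max and t_min series must have equal length", call. = FALSE)
  }
  if (any(t_min_series > t_max_series, na.rm = TRUE)) {
    stop("t_min > t_max on some day", call. = FALSE)
  }
  m <- if (formula_variant == "standard") (t_max_series + t_min_series) / 2
       else (t_max_series - t_min_series) / 2
  m <- m[!is.na(m)]
  if (kind == "cooling") sum((m - CDD_BASE)[m > CDD_BASE])
  else sum((HDD_BASE - m)[m < HDD_BASE])
}

#' Build the yearly metrics table
#'
#' One row per (region, complete calendar year) with every metric family:
#' tropical nights and polar days; days above the heat thresholds and
#' below the cold thresholds (strict, on `measure`); expected exceedance
#' fractions `1 - F_n(t)` / `F_n(t)` from a reference-period ECDF;
#' cooling and heating degree days; days above/below the per-region
#' percentile thresholds; and the threshold temperatures themselves.
#' Partial years at the series edges are dropped with a warning.
#'
#' @param daily A daily measures table (see [build_daily_table()]).
#' @param thresholds A [percentile_thresholds()] table (same regions).
#' @param measure Daily measure for absolute-threshold and ECDF metrics;
#'   default `"t_mean"`.
#' @param percentile_measure Daily measure compared against the
#'   percentile thresholds; defaults to the measure the thresholds were
#'   computed from.
#' @param heat_thresholds,cold_thresholds Absolute threshold sets (degC).
#' @param degree_day_variant Passed to [degree_days()].
#' @param ecdf_reference `"reference"` (default): the ECDF is taken over
#'   the same reference window as the percentile thresholds;
#'   `"focal"`: over the focal year itself (making the metric a rescaled
#'   day count).
#' @return A tibble, one row per (region_id, year).
#' @export
build_yearly_table <- function(daily, thresholds,
                               measure = "t_mean",
                               percentile_measure = NULL,
                               heat_thresholds = HEAT_THRESHOLDS,
                               cold_thresholds = COLD_THRESHOLDS,
                               degree_day_variant = c("standard", "as_printed"),
                               ecdf_reference = c("reference", "focal")) {
  degree_day_variant <- match.arg(degree_day_variant)
  ecdf_reference <- match.arg(ecdf_reference)
  stopifnot(inherits(thresholds, "percentile_table"))
  if (is.null(percentile_measure)) {
    percentile_measure <- attr(thresholds, "measure")
  }
  ref_years <- attr(thresholds, "reference_years")
  ids <- sort(unique(daily$region_id))

  rows <- list()
  for (id in ids) {
    d <- daily[daily$region_id == id, ]
    dyr <- as.integer(format(d$date, "%Y"))
    ref_series <- if (ecdf_reference == "reference") {
      d[[measure]][dyr >= ref_years[1L] & dyr <= ref_years[2L]]
    } else NULL
    for (y in sort(unique(dyr))) {
      dy <- d[dyr == y, ]
      n_expected <- days_in_year(y)
      if (nrow(dy) != n_expected) {
        warning("dropping partial year ", y, " for region ", id, " (",
                nrow(dy), "/", n_expected, " days)", call. = FALSE)
        next
      }
      ref_y <- if (ecdf_reference == "focal") dy[[measure]] else ref_series
      rows[[length(rows) + 1L]] <- yearly_record(
        dy, id, y, thresholds, measure, percentile_measure,
        heat_thresholds, cold_thresholds, degree_day_variant, ref_y)
    }
  }
  if (length(rows) == 0L) stop("no complete calendar years", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "degree_day_variant") <- degree_day_variant
  attr(out, "reference_years") <- ref_years
  out
}

yearly_record <- function(dy, id, y, thresholds, measure,
                          percentile_measure, heat_thresholds,
                          cold_thresholds, degree_day_variant, ref_series) {
  x <- dy[[measure]]
  rec <- tibble::tibble(
    region_id = id, year = y, n = nrow(dy),
    tropical_nights = sum(dy$t_min > TROPICAL_NIGHT_TMIN, na.rm = TRUE),
    polar_days = sum(dy$t_max < POLAR_DAY_TMAX, na.rm = TRUE)
  )
  for (t in heat_thresholds) {
    rec[[paste0("days_above_", thr_label(t))]] <- sum(x > t, na.rm = TRUE)
  }
  for (t in cold_thresholds) {
    rec[[paste0("days_below_", thr_label(t))]] <- sum(x < t, na.rm = TRUE)
  }
  for (t in heat_thresholds) {
    rec[[paste0("expected_above_", thr_label(t))]] <-
      1 - ecdf_fraction(ref_series, t)
  }
  for (t in cold_thresholds) {
    rec[[paste0("expected_below_", thr_label(t))]] <-
      ecdf_fraction(ref_series, t)
  }
  rec$cdd <- degree_days(dy$t_max, dy$t_min, "cooling", degree_day_variant)
  rec$hdd <- degree_days(dy$t_max, dy$t_min, "heating", degree_day_variant)
  px <- dy[[percentile_measure]]
  th <- thresholds[thresholds$region_id == id, ]
  for (p in UPPER_PERCENTILES) {
    tt <- th$value[abs(th$p - p) < 1e-9][1L]
    rec[[paste0("days_above_", pct_label(p))]] <- sum(px > tt, na.rm = TRUE)
  }
  for (p in LOWER_PERCENTILES) {
    tt <- th$value[abs(th$p - p) < 1e-9][1L]
    rec[[paste0("days_below_", pct_label(p))]] <- sum(px < tt, na.rm = TRUE)
  }
  for (p in sort(th$p)) {
    rec[[paste0("t_at_", pct_label(p))]] <- th$value[abs(th$p - p) < 1e-9][1L]
  }
  rec
}
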