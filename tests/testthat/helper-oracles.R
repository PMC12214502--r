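# Independent brute-force oracles used to cross-check the implementation.
# These are written from first principles and share no code with the
# package internals.

# --- point-in-polygon: ray casting with explicit boundary handling ------

on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-9) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

# TRUE if (px, py) is inside or on the boundary of a closed ring
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  for (i in seq_len(n)) {
    if (on_segment(px, py, ring[i, 1], ring[i, 2],
                   ring[i + 1, 1], ring[i + 1, 2])) return(TRUE)
  }
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

# per-cell assignment oracle: first containing region in lexicographic
# region_id order wins; masked cells never assigned
assignment_oracle <- function(grid, regions) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  owner <- matrix(NA_character_, nlat, nlon)
  ids <- sort(regions$region_id)
  for (j in seq_len(nlon)) for (i in seq_len(nlat)) {
    if (grid$mask[i, j]) next
    for (id in ids) {
      ring <- regions$geometry[[match(id, regions$region_id)]][[1L]]
      if (pip_oracle(grid$lon[j], grid$lat[i], ring)) {
        owner[i, j] <- id
        break
      }
    }
  }
  owner
}

# --- maximal-run enumeration oracle ------------------------------------

runs_oracle <- function(flags, min_length) {
  flags[is.na(flags)] <- FALSE
  n <- length(flags)
  out <- NULL
  for (s in seq_len(n)) {
    if (!flags[s]) next
    if (s > 1L && flags[s - 1L]) next        # not a run start
    e <- s
    while (e < n && flags[e + 1L]) e <- e + 1L
    if (e - s + 1L >= min_length) out <- rbind(out, c(s, e, e - s + 1L))
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0), length = integer(0))
  } else {
    data.frame(start = out[, 1L], end = out[, 2L], length = out[, 3L])
  }
}

# --- naive per-day yearly metrics oracle --------------------------------

naive_yearly_metrics <- function(t_min, t_max, t_mean, ref_series,
                                 th_p, th_v,
                                 heat = c(20, 25, 30, 35, 40, 45),
                                 cold = c(-20, -15, -10, -5, 0, 5),
                                 variant = "standard",
                                 percentile_series = t_mean) {
  n <- length(t_mean)
  out <- list(n = n)
  cnt <- function(f) { k <- 0L; for (i in seq_len(n)) if (f(i)) k <- k + 1L; k }
  out$tropical_nights <- cnt(function(i) !is.na(t_min[i]) && t_min[i] > 20)
  out$polar_days <- cnt(function(i) !is.na(t_max[i]) && t_max[i] < 10)
  for (t in heat) {
    out[[paste0("days_above_", gsub("-", "m", t))]] <-
      cnt(function(i) !is.na(t_mean[i]) && t_mean[i] > t)
  }
  for (t in cold) {
    out[[paste0("days_below_", gsub("-", "m", t))]] <-
      cnt(function(i) !is.na(t_mean[i]) && t_mean[i] < t)
  }
  fr <- function(t) {
    k <- 0L
    for (v in ref_series) if (!is.na(v) && v <= t) k <- k + 1L
    k / sum(!is.na(ref_series))
  }
  for (t in heat) {
    out[[paste0("expected_above_", gsub("-", "m", t))]] <- 1 - fr(t)
  }
  for (t in cold) {
    out[[paste0("expected_below_", gsub("-", "m", t))]] <- fr(t)
  }
  cdd <- 0; hdd <- 0
  for (i in seq_len(n)) {
    m <- if (variant == "standard") (t_max[i] + t_min[i]) / 2 else
      (t_max[i] - t_min[i]) / 2
    if (is.na(m)) next
    if (m > 24) cdd <- cdd + (m - 24)
    if (m < 20) hdd <- hdd + (20 - m)
  }
  out$cdd <- cdd; out$hdd <- hdd
  for (k in seq_along(th_p)) {
    p <- th_p[k]; tv <- th_v[k]
    lbl <- sprintf("p%02d", round(p * 100))
    if (p > 0.5) {
      out[[paste0("days_above_", lbl)]] <-
        cnt(function(i) !is.na(percentile_series[i]) && percentile_series[i] > tv)
    } else {
      out[[paste0("days_below_", lbl)]] <-
        cnt(function(i) !is.na(percentile_series[i]) && percentile_series[i] < tv)
    }
    out[[paste0("t_at_", lbl)]] <- tv
  }
  out
}

# --- small fixture builders ---------------------------------------------

# a daily table for one region and a full calendar year
make_year_daily <- function(region_id, year, t_mean, spread = 5) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  stopifnot(length(t_mean) == length(dates))
  tibble::tibble(region_id = region_id, date = dates,
                 t_min = t_mean - spread, t_max = t_mean + spread,
                 t_mean = t_mean)
}

zero_noise_params <- function(baseline = 10, ...) {
  climate_sim_params(baseline_mean = baseline, seasonal_amplitude = 0,
                     diurnal_amplitude = 0, noise_sd = 0,
                     noise_autocorr = 0, spatial_gradient = 0,
                     missing_fraction = 0, seed = 1, ...)
}
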