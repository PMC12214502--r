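# Synthetic climate, region and population generators.
#
# These emulate the statistical structure of reanalysis-style inputs --
# seasonal and diurnal cycles, temporally autocorrelated weather noise, a
# latitudinal gradient, a static ocean mask -- so the whole pipeline can be
# exercised and tested without any external download.

# day-of-year (0-based, fractional) at which the seasonal sinusoid peaks:
# mid-July, the Northern-Hemisphere convention
SEASONAL_PEAK_DOY <- 195.5
# UTC hour at which the diurnal sinusoid peaks (mid-afternoon)
DIURNAL_PEAK_HOUR <- 15

#' Parameters of the synthetic hourly climate generator
#'
#' The generated field at cell `(lat, lon)` and time `t` is
#' `baseline_mean + seasonal + diurnal + gradient + noise`, where the
#' seasonal term is a sinusoid with period one year peaking mid-July, the
#' diurnal term a sinusoid with period 24 h peaking at 15:00 UTC, the
#' gradient is linear in latitude, and the noise is a stationary AR(1)
#' process generated independently per cell.  Temporal autocorrelation in
#' the noise is what makes multi-day threshold exceedances (waves) occur at
#' realistic rates.
#'
#' Defaults emulate a mid-latitude European temperate climate: 11 degC
#' annual mean, 10 degC seasonal half-amplitude, 4 degC diurnal
#' half-amplitude, day-to-day weather anomalies with 3 degC marginal
#' standard deviation and strong hour-to-hour persistence.
#'
#' @param baseline_mean Long-run mean temperature (degC).
#' @param seasonal_amplitude Half-amplitude of the annual cycle (degC).
#' @param diurnal_amplitude Half-amplitude of the daily cycle (degC).
#' @param noise_sd Marginal standard deviation of the AR(1) noise (degC);
#'   must be >= 0.
#' @param noise_autocorr Lag-1 (hourly) autocorrelation of the noise, in
#'   `[0, 1)`.
#' @param spatial_gradient Linear trend in degC per degree latitude
#'   (negative: colder towards the north), centred on the extent midpoint.
#' @param missing_fraction Fraction of cells masked as permanently missing
#'   (emulating ocean cells in a land-only product), in `[0, 1)`.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return A list of class `climate_sim_params`.
#' @export
climate_sim_params <- function(baseline_mean = 11,
                               seasonal_amplitude = 10,
                               diurnal_amplitude = 4,
                               noise_sd = 3,
                               noise_autocorr = 0.95,
                               spatial_gradient = -0.6,
                               missing_fraction = 0.1,
                               seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_autocorr < 0 || noise_autocorr >= 1) {
    stop("`noise_autocorr` must be in [0, 1)", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(baseline_mean = baseline_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 noise_sd = noise_sd,
                 noise_autocorr = noise_autocorr,
                 spatial_gradient = spatial_gradient,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "climate_sim_params")
}

#' Generate a synthetic hourly temperature grid
#'
#' Produces one value per (cell, hour) for every hour of every calendar
#' date in `[start_date, end_date]` (proleptic Gregorian, leap days
#' included, hours stamped in UTC).  See [climate_sim_params()] for the
#' signal model.
#'
#' @param extent A [grid_extent()].
#' @param resolution Cell size in degrees (> 0).
#' @param start_date,end_date First and last calendar date (inclusive),
#'   `Date` or `"YYYY-MM-DD"` strings.
#' @param params A [climate_sim_params()] object.
#' @param varname Variable name recorded on the output grid.
#' @return An [hourly_grid()] object in degC.
#' @export
#' @examples
#' g <- generate_hourly_grid(grid_extent(0, 2, 40, 42), 1,
#'                           "2000-06-01", "2000-06-07",
#'                           climate_sim_params(noise_sd = 0, seed = 7))
generate_hourly_grid <- function(extent, resolution, start_date, end_date,
                                 params = climate_sim_params(),
                                 varname = "temperature") {
  stopifnot(inherits(params, "climate_sim_params"))
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date > end_date) {
    stop("empty date range: require start_date <= end_date", call. = FALSE)
  }
  ax <- extent_axes(extent, resolution)
  lat <- ax$lat; lon <- ax$lon
  nlat <- length(lat); nlon <- length(lon); ncell <- nlat * nlon

  dates <- seq(start_date, end_date, by = "day")
  ndays <- length(dates)
  ntime <- ndays * 24L
  time <- as.POSIXct(as.numeric(dates[1L]) * 86400 + 3600 * (seq_len(ntime) - 1L),
                     origin = "1970-01-01", tz = "UTC")

  # deterministic signal shared by all cells
  doy <- as.POSIXlt(dates)$yday                       # 0-based
  hours <- 0:23
  doy_frac <- rep(doy, each = 24L) + rep(hours, ndays) / 24
  seasonal <- params$seasonal_amplitude *
    cos(2 * pi * (doy_frac - SEASONAL_PEAK_DOY) / 365.25)
  diurnal <- params$diurnal_amplitude *
    cos(2 * pi * (rep(hours, ndays) - DIURNAL_PEAK_HOUR) / 24)
  tc <- params$baseline_mean + seasonal + diurnal

  lat_mid <- (extent[["lat_min"]] + extent[["lat_max"]]) / 2
  cell_lat <- rep(lat, times = nlon)                  # flat index: lat fastest
  grad <- params$spatial_gradient * (cell_lat - lat_mid)

  rho <- params$noise_autocorr
  sd_innov <- params$noise_sd * sqrt(1 - rho^2)

  vmat <- matrix(NA_real_, ntime, ncell)
  with_seed(params$seed, {
    n_missing <- floor(params$missing_fraction * ncell)
    masked <- if (n_missing > 0L) sample.int(ncell, n_missing) else integer(0)
    is_masked <- logical(ncell); is_masked[masked] <- TRUE
    for (j in seq_len(ncell)) {
      if (is_masked[j]) next
      col <- tc + grad[j]
      if (params$noise_sd > 0) {
        e <- rnorm(ntime, sd = sd_innov)
        if (rho > 0) {
          # stationary start: x_1 = rho*x_0 + e_1 with x_0 ~ N(0, noise_sd)
          e[1L] <- e[1L] + rho * rnorm(1L, sd = params$noise_sd)
          e <- as.numeric(stats::filter(e, rho, method = "recursive"))
        }
        col <- col + e
      }
      vmat[, j] <- col
    }
    mask <- matrix(FALSE, nlat, nlon)
    mask[masked] <- TRUE
    dim(vmat) <- c(ntime, nlat, nlon)
    hourly_grid(lat, lon, time, vmat, mask = mask, units = "degC",
                varname = varname)
  })
}

#' Generate a synthetic region set tiling an extent
#'
#' Partitions the extent into `n_regions` disjoint rectangles by recursive
#' bisection: at each step the current box is split across its longer side
#' in proportion to the number of regions assigned to each half.  With
#' `jitter = 0` the split fractions are exact, so `n_regions = 4` on a
#' square extent gives the four quadrants; with `jitter > 0` the split
#' position is perturbed by a seeded uniform draw, producing randomised
#' layouts whose union still equals the extent.
#'
#' @param extent A [grid_extent()].
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed for the jitter draws.
#' @param jitter Relative perturbation of each split fraction, in
#'   `[0, 0.9]`; 0 gives a deterministic proportional tiling.
#' @param resolution Optional companion-grid cell size; if supplied,
#'   requesting more regions than grid cells is an error.
#' @return A [region_set()] with identifiers `"R001"`, `"R002"`, ...
#' @export
generate_region_set <- function(extent, n_regions, seed = 1L, jitter = 0,
                                resolution = NULL) {
  stopifnot(inherits(extent, "grid_extent"))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("`n_regions` must be >= 1", call. = FALSE)
  if (jitter < 0 || jitter > 0.9) stop("`jitter` must be in [0, 0.9]", call. = FALSE)
  if (!is.null(resolution)) {
    ax <- extent_axes(extent, resolution)
    if (n_regions > length(ax$lat) * length(ax$lon)) {
      stop("n_regions exceeds the cell count of the companion grid",
           call. = FALSE)
    }
  }
  boxes <- with_seed(seed, split_box(unclass(extent)[1:4], n_regions, jitter))
  geometry <- lapply(boxes, function(b) {
    matrix(c(b[1L], b[3L],  b[2L], b[3L],  b[2L], b[4L],
             b[1L], b[4L],  b[1L], b[3L]), ncol = 2L, byrow = TRUE)
  })
  region_set(sprintf("R%03d", seq_len(n_regions)), geometry,
             level = "synthetic")
}

# recursive bisection of box c(lon_min, lon_max, lat_min, lat_max)
split_box <- function(box, n, jitter) {
  if (n == 1L) return(list(box))
  n1 <- n %/% 2L
  f <- n1 / n
  if (jitter > 0) f <- f * (1 + jitter * runif(1L, -1, 1))
  f <- min(max(f, 0.05), 0.95)
  wx <- box[2L] - box[1L]; wy <- box[4L] - box[3L]
  if (wx >= wy) {  # split along longitude
    cut <- box[1L] + f * wx
    b1 <- c(box[1L], cut, box[3L], box[4L])
    b2 <- c(cut, box[2L], box[3L], box[4L])
  } else {
    cut <- box[3L] + f * wy
    b1 <- c(box[1L], box[2L], box[3L], cut)
    b2 <- c(box[1L], box[2L], cut, box[4L])
  }
  c(split_box(b1, n1, jitter), split_box(b2, n - n1, jitter))
}

#' Generate a synthetic gridded population surface
#'
#' A non-negative, spatially smooth log-Gaussian density surface per epoch
#' year, emulating the multi-year release cadence of gridded population
#' products.  Successive epochs are strongly correlated (slow demographic
#' change).
#'
#' @param extent A [grid_extent()].
#' @param resolution Cell size in degrees (> 0).
#' @param epoch_years Integer years, strictly increasing (e.g.
#'   `seq(2000, 2020, 5)`).
#' @param seed Integer RNG seed.
#' @param uniform If `TRUE`, every cell holds the same value
#'   (`mean_density`) in every epoch.
#' @param mean_density Target mean persons per cell.
#' @return A [population_grid()].
#' @export
generate_population_grid <- function(extent, resolution, epoch_years,
                                     seed = 1L, uniform = FALSE,
                                     mean_density = 100) {
  ax <- extent_axes(extent, resolution)
  nlat <- length(ax$lat); nlon <- length(ax$lon)
  epoch_years <- as.integer(epoch_years)
  if (length(epoch_years) == 0L || is.unsorted(epoch_years, strictly = TRUE)) {
    stop("`epoch_years` must be non-empty and strictly increasing",
         call. = FALSE)
  }
  ne <- length(epoch_years)
  values <- array(NA_real_, c(ne, nlat, nlon))
  if (uniform) {
    values[] <- mean_density
  } else {
    sigma <- 0.8   # log-scale spread: ~order-of-magnitude density contrasts
    rho_e <- 0.95  # epoch-to-epoch persistence
    with_seed(seed, {
      z <- smooth2d(matrix(rnorm(nlat * nlon), nlat, nlon))
      z <- z / stats::sd(z)
      for (e in seq_len(ne)) {
        if (e > 1L) {
          innov <- smooth2d(matrix(rnorm(nlat * nlon), nlat, nlon))
          innov <- innov / stats::sd(innov)
          z <- rho_e * z + sqrt(1 - rho_e^2) * innov
        }
        values[e, , ] <- mean_density * exp(sigma * z - sigma^2 / 2)
      }
    })
  }
  population_grid(ax$lat, ax$lon, epoch_years, values)
}

# two passes of a 3x3 box filter with edge replication
smooth2d <- function(m, passes = 2L) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) x[c(1L, seq_len(nrow(x)), nrow(x)),
                       c(1L, seq_len(ncol(x)), ncol(x)), drop = FALSE]
  for (k in seq_len(passes)) {
    p <- pad(m)
    acc <- matrix(0, nr, nc)
    for (di in 0:2) for (dj in 0:2) {
      acc <- acc + p[di + seq_len(nr), dj + seq_len(nc)]
    }
    m <- acc / 9
  }
  m
}
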