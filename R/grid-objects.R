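#' Geographic extent helper
#'
#' A rectangular lon/lat bounding box used by the synthetic generators.
#'
#' @param lon_min,lon_max,lat_min,lat_max Bounding box edges in decimal
#'   degrees; `lon_min < lon_max`, `lat_min < lat_max`.
#' @return A named numeric vector of class `grid_extent`.
#' @export
#' @examples
#' grid_extent(0, 10, 40, 50)
grid_extent <- function(lon_min, lon_max, lat_min, lat_max) {
  for (v in c(lon_min, lon_max, lat_min, lat_max)) stopifnot_scalar_number(v, "extent edge")
  if (lon_min >= lon_max || lat_min >= lat_max) {
    stop("degenerate extent: require lon_min < lon_max and lat_min < lat_max",
         call. = FALSE)
  }
  structure(c(lon_min = lon_min, lon_max = lon_max,
              lat_min = lat_min, lat_max = lat_max),
            class = "grid_extent")
}

# cell-center axes for an extent at a given resolution
extent_axes <- function(extent, resolution) {
  stopifnot_scalar_number(resolution, "resolution")
  if (resolution <= 0) stop("`resolution` must be positive", call. = FALSE)
  nlon <- floor(round((extent[["lon_max"]] - extent[["lon_min"]]) / resolution, 8))
  nlat <- floor(round((extent[["lat_max"]] - extent[["lat_min"]]) / resolution, 8))
  if (nlon < 1L || nlat < 1L) {
    stop("resolution larger than extent: no grid cell fits", call. = FALSE)
  }
  list(
    lon = extent[["lon_min"]] + resolution * (seq_len(nlon) - 0.5),
    lat = extent[["lat_min"]] + resolution * (seq_len(nlat) - 0.5)
  )
}

#' Construct an hourly gridded series
#'
#' Container for hourly values on a regular lon/lat grid with a static
#' missing-cell mask (e.g. ocean cells in land-only products).  Values are
#' stored as a `[time, lat, lon]` array; masked cells are `NA` at every
#' timestamp.
#'
#' @param lat,lon Cell-center coordinates, ascending, regularly spaced
#'   (degrees).
#' @param time Hourly `POSIXct` timestamps (UTC), strictly increasing.
#' @param values Numeric array with dim `c(length(time), length(lat),
#'   length(lon))`, in the units given by `units`.
#' @param mask Logical `length(lat) x length(lon)` matrix, `TRUE` where the
#'   cell is permanently missing.  Derived from `values` if omitted.
#' @param units Unit string, `"degC"` by default.
#' @param varname Name of the physical variable (e.g. `"temperature"`,
#'   `"utci"`).
#' @return An object of class `hourly_grid`.
#' @export
hourly_grid <- function(lat, lon, time, values, mask = NULL,
                        units = "degC", varname = "temperature") {
  if (!is_regular(lat) || !is_regular(lon)) {
    stop("grid axes must be regularly spaced", call. = FALSE)
  }
  if (is.unsorted(lat, strictly = TRUE) || is.unsorted(lon, strictly = TRUE)) {
    stop("grid axes must be strictly ascending", call. = FALSE)
  }
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct", call. = FALSE)
  dt <- diff(as.numeric(time))
  if (length(dt) && any(abs(dt - 3600) > 1e-6)) {
    stop("timestamps must be strictly increasing with an hourly step",
         call. = FALSE)
  }
  dv <- dim(values)
  if (length(dv) != 3L || dv[1L] != length(time) ||
      dv[2L] != length(lat) || dv[3L] != length(lon)) {
    stop("`values` must have dim c(n_time, n_lat, n_lon)", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- apply(is.na(values), c(2L, 3L), all)
  }
  structure(
    list(lat = as.numeric(lat), lon = as.numeric(lon), time = time,
         values = values, mask = mask, units = units, varname = varname),
    class = "hourly_grid"
  )
}

#' @export
print.hourly_grid <- function(x, ...) {
  cat(sprintf("<hourly_grid> %s [%s]\n", x$varname, x$units))
  cat(sprintf("  grid: %d lat x %d lon (%d masked cells)\n",
              length(x$lat), length(x$lon), sum(x$mask)))
  cat(sprintf("  time: %s .. %s (%d hourly steps, UTC)\n",
              format(x$time[1L], tz = "UTC"),
              format(x$time[length(x$time)], tz = "UTC"), length(x$time)))
  invisible(x)
}

#' Construct a region set
#'
#' Polygons with unique region identifiers: the spatial units of every
#' output table (administrative regions such as NUTS 2/3, or synthetic
#' tiles).
#'
#' @param region_id Character vector of unique identifiers.
#' @param geometry List, one element per region; each element is a list of
#'   rings, each ring a closed two-column (lon, lat) matrix.  The first
#'   ring is the exterior boundary, any further rings are holes.
#' @param level Label for the spatial level (e.g. `"nuts2"`, `"synthetic"`).
#' @return A tibble of class `region_set` with columns `region_id`, `level`
#'   and a `geometry` list-column.
#' @export
region_set <- function(region_id, geometry, level = "synthetic") {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id)) {
    stop("duplicate region_id: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.matrix(geometry)) geometry <- list(geometry)
  if (length(geometry) != length(region_id)) {
    stop("`geometry` must have one element per region", call. = FALSE)
  }
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2L || nrow(ring) < 4L) {
        stop("each ring must be an n x 2 (lon, lat) matrix with >= 4 vertices",
             call. = FALSE)
      }
      # repair an unclosed ring by appending the first vertex
      if (any(ring[1L, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
      unname(ring)
    })
  })
  out <- tibble::tibble(region_id = region_id, level = level,
                        geometry = geometry)
  class(out) <- c("region_set", class(out))
  out
}

#' Construct a population grid
#'
#' Gridded population counts at one or more epoch years (the multi-year
#' release cadence of global gridded population products).
#'
#' @param lat,lon Cell-center coordinates, ascending (degrees).
#' @param epochs Integer epoch years, strictly increasing.
#' @param values Non-negative numeric array with dim
#'   `c(length(epochs), length(lat), length(lon))` (persons per cell).
#' @return An object of class `population_grid`.
#' @export
population_grid <- function(lat, lon, epochs, values) {
  epochs <- as.integer(epochs)
  if (length(epochs) == 0L || is.unsorted(epochs, strictly = TRUE)) {
    stop("`epochs` must be non-empty and strictly increasing", call. = FALSE)
  }
  dv <- dim(values)
  if (length(dv) != 3L || dv[1L] != length(epochs) ||
      dv[2L] != length(lat) || dv[3L] != length(lon)) {
    stop("`values` must have dim c(n_epochs, n_lat, n_lon)", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("population values must be non-negative", call. = FALSE)
  }
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 epochs = epochs, values = values),
            class = "population_grid")
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf("<population_grid> %d lat x %d lon, epochs: %s\n",
              length(x$lat), length(x$lon), paste(x$epochs, collapse = ", ")))
  invisible(x)
}
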