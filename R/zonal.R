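# Zonal aggregation: assigning grid cells to regions and computing
# equal-weight and population-weighted spatial means.

#' Assign grid cells to regions
#'
#' A cell belongs to a region iff its center lies inside (or on the
#' boundary of) the region polygon.  The center rule is deterministic and
#' partition-forming, and matches equal per-cell weighting: no fractional
#' area weights.  A cell center falling exactly on a shared boundary is
#' assigned to the region with the lexicographically smallest `region_id`.
#' Masked (permanently missing) cells are never assigned.  Regions that
#' capture no valid cell are reported with a warning and yield missing
#' values downstream.
#'
#' @param grid An [hourly_grid()] (only its axes and mask are used).
#' @param regions A [region_set()].
#' @return An object of class `cell_assignment`: a named list of flat cell
#'   indices (into the `lat x lon` matrix, lat varying fastest) per
#'   region, with the grid axes attached.
#' @export
assign_cells <- function(grid, regions) {
  stopifnot(inherits(grid, "hourly_grid"), inherits(regions, "region_set"))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  px <- rep(grid$lon, each = nlat)   # flat index: lat fastest
  py <- rep(grid$lat, times = nlon)
  valid <- !as.vector(grid$mask)

  ids <- regions$region_id
  ord <- order(ids)                  # lexicographic tie-break order
  owner <- rep(NA_character_, nlat * nlon)
  for (k in ord) {
    inside <- polygon_contains(regions$geometry[[k]], px, py)
    take <- inside & valid & is.na(owner)
    owner[take] <- ids[k]
  }

  cells <- lapply(ids, function(id) which(!is.na(owner) & owner == id))
  names(cells) <- ids
  n_cells <- lengths(cells)
  if (all(n_cells == 0L)) {
    stop("no region contains any valid grid cell center", call. = FALSE)
  }
  if (any(n_cells == 0L)) {
    warning("regions with zero valid cells (all measures will be missing): ",
            paste(ids[n_cells == 0L], collapse = ", "), call. = FALSE)
  }
  structure(list(cells = cells, lat = grid$lat, lon = grid$lon,
                 dim = c(nlat, nlon)),
            class = "cell_assignment")
}

# TRUE where point (px, py) is inside or on the boundary of a polygon given
# as a list of rings (first exterior, rest holes).  Points strictly inside
# a hole are excluded; hole boundaries count as inside the region.
polygon_contains <- function(rings, px, py) {
  ext <- rings[[1L]]
  code <- sp::point.in.polygon(px, py, ext[, 1L], ext[, 2L])
  inside <- code >= 1L                       # 1 interior, 2 edge, 3 vertex
  if (length(rings) > 1L) {
    for (h in rings[-1L]) {
      hc <- sp::point.in.polygon(px, py, h[, 1L], h[, 2L])
      inside <- inside & hc != 1L            # strictly inside hole -> out
    }
  }
  inside
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat(sprintf("<cell_assignment> %d regions on a %d x %d grid\n",
              length(x$cells), x$dim[1L], x$dim[2L]))
  print(lengths(x$cells))
  invisible(x)
}

#' Equal-weight zonal mean of a field slice
#'
#' Arithmetic mean over the region's included, non-missing cells.  All
#' cells are weighted equally (no area or latitude-cosine weighting).
#'
#' @param field_slice Numeric `lat x lon` matrix.
#' @param assignment A [assign_cells()] result.
#' @param region_id Single region identifier present in `assignment`.
#' @return The mean in the field's units, or `NA` if the region has no
#'   valid value in this slice.
#' @export
zonal_mean <- function(field_slice, assignment, region_id) {
  cells <- assignment_cells(assignment, region_id)
  if (length(cells) == 0L) return(NA_real_)
  v <- field_slice[cells]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}

#' Population-weighted zonal mean of a field slice
#'
#' Weighted mean `sum(w_i x_i) / sum(w_i)` over the region's included
#' cells, with weights given by a population surface already aligned to
#' the climate grid (see [align_population()]).
#'
#' @param field_slice Numeric `lat x lon` matrix of field values.
#' @param pop_slice Numeric `lat x lon` matrix of non-negative population
#'   weights on the same grid.
#' @param assignment A [assign_cells()] result.
#' @param region_id Single region identifier present in `assignment`.
#' @return The weighted mean, or `NA` (with a warning) if the region's
#'   total population weight is zero.
#' @export
zonal_population_weighted_mean <- function(field_slice, pop_slice,
                                           assignment, region_id) {
  cells <- assignment_cells(assignment, region_id)
  if (length(cells) == 0L) return(NA_real_)
  w <- pop_slice[cells]
  if (any(w < 0, na.rm = TRUE)) {
    stop("negative population weights", call. = FALSE)
  }
  v <- field_slice[cells]
  ok <- !is.na(v) & !is.na(w)
  if (sum(w[ok]) == 0) {
    warning("zero total population weight in region ", region_id,
            "; population-weighted mean is missing", call. = FALSE)
    return(NA_real_)
  }
  sum(w[ok] * v[ok]) / sum(w[ok])
}

assignment_cells <- function(assignment, region_id) {
  stopifnot(inherits(assignment, "cell_assignment"))
  if (length(region_id) != 1L || !region_id %in% names(assignment$cells)) {
    stop("unknown region_id: ", region_id, call. = FALSE)
  }
  assignment$cells[[region_id]]
}

#' Select the population epoch for a given year
#'
#' Population products are released at multi-year epochs; a year is
#' weighted with the most recent epoch not later than the year itself
#' (never a future epoch), e.g. 2004 uses the 2000 epoch and 2006 the 2005
#' epoch with epochs every 5 years.
#'
#' @param year Integer calendar year.
#' @param epochs Sorted integer epoch years.
#' @return The selected epoch year, or `NA` if `year` precedes the first
#'   epoch (no population available; callers emit unweighted-only rows).
#' @export
#' @examples
#' select_population_epoch(2004, c(2000, 2005, 2010, 2015, 2020))  # 2000
#' select_population_epoch(2006, c(2000, 2005, 2010, 2015, 2020))  # 2005
select_population_epoch <- function(year, epochs) {
  stopifnot(length(year) == 1L, length(epochs) >= 1L)
  epochs <- sort(as.integer(epochs))
  year <- as.integer(year)
  ok <- epochs[epochs <= year]
  if (length(ok) == 0L) return(NA_integer_)
  max(ok)
}

#' Align a population grid to a climate grid
#'
#' Population is an extensive quantity: each population cell is assigned
#' by nearest-neighbour to the climate cell whose center is closest, and
#' counts are summed within each climate cell footprint.
#'
#' @param population A [population_grid()].
#' @param grid An [hourly_grid()] providing the target axes.
#' @param epoch_year One of `population$epochs`.
#' @return A `lat x lon` matrix of summed population on the climate grid
#'   (0 where no population cell maps).
#' @export
align_population <- function(population, grid, epoch_year) {
  stopifnot(inherits(population, "population_grid"),
            inherits(grid, "hourly_grid"))
  e <- match(as.integer(epoch_year), population$epochs)
  if (is.na(e)) stop("epoch_year ", epoch_year, " not present", call. = FALSE)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  res_lat <- if (nlat > 1L) grid$lat[2L] - grid$lat[1L] else
    diff(range(population$lat)) + 1
  res_lon <- if (nlon > 1L) grid$lon[2L] - grid$lon[1L] else
    diff(range(population$lon)) + 1
  i <- round((population$lat - grid$lat[1L]) / res_lat) + 1L
  j <- round((population$lon - grid$lon[1L]) / res_lon) + 1L
  pv <- population$values[e, , , drop = TRUE]
  if (is.null(dim(pv))) pv <- matrix(pv, length(population$lat))
  out <- matrix(0, nlat, nlon)
  ii <- rep(i, times = length(j)); jj <- rep(j, each = length(i))
  keep <- ii >= 1L & ii <= nlat & jj >= 1L & jj <= nlon
  if (any(keep)) {
    flat <- (jj[keep] - 1L) * nlat + ii[keep]
    sums <- rowsum(as.vector(pv)[keep], flat)
    out[as.integer(rownames(sums))] <- sums[, 1L]
  }
  out
}
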