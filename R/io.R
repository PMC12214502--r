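# Readers and writers for the pipeline's standard formats: NetCDF grids,
# GeoJSON regions, and the three output CSV tables, plus QC checks and a
# machine-readable codebook.

#' Write an hourly grid to NetCDF
#'
#' Dimensions `lon`, `lat`, `time` (hours since 1900-01-01 00:00 UTC);
#' masked cells are stored as the fill value.
#'
#' @param grid An [hourly_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_nc <- function(grid, path) {
  stopifnot(inherits(grid, "hourly_grid"))
  origin <- as.POSIXct("1900-01-01 00:00:00", tz = "UTC")
  hours <- as.numeric(difftime(grid$time, origin, units = "hours"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dim_time <- ncdf4::ncdim_def("time", "hours since 1900-01-01 00:00:00",
                               hours, unlim = TRUE)
  var <- ncdf4::ncvar_def(grid$varname, grid$units,
                          list(dim_lon, dim_lat, dim_time),
                          missval = 1e30, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  # values are [time, lat, lon]; NetCDF wants [lon, lat, time]
  ncdf4::ncvar_put(nc, var, aperm(grid$values, c(3L, 2L, 1L)))
  invisible(path)
}

#' Read an hourly grid from NetCDF
#'
#' Expects `time`/`lat`/`lon` coordinates (any order, common aliases
#' `latitude`/`longitude` accepted) and a single data variable.  The grid
#' must be regular and the time step hourly.  A variable with a Kelvin
#' units attribute is converted to degC.
#'
#' @param path NetCDF file path.
#' @param varname Variable to read; defaults to the file's only data
#'   variable.
#' @return An [hourly_grid()].
#' @export
read_grid_file <- function(path, varname = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  dims <- names(nc$dim)
  find_dim <- function(aliases, what) {
    hit <- dims[dims %in% aliases]
    if (length(hit) == 0L) {
      stop("missing coordinate '", what, "' in ", path,
           " (found: ", paste(dims, collapse = ", "), ")", call. = FALSE)
    }
    hit[1L]
  }
  d_time <- find_dim(c("time", "valid_time"), "time")
  d_lat <- find_dim(c("lat", "latitude"), "lat")
  d_lon <- find_dim(c("lon", "longitude"), "lon")
  if (is.null(varname)) {
    varname <- names(nc$var)[1L]
    if (is.null(varname)) stop("no data variable in ", path, call. = FALSE)
  }
  v <- nc$var[[varname]]
  if (is.null(v)) stop("variable ", varname, " not in ", path, call. = FALSE)
  units <- v$units
  if (is.null(units) || !nzchar(units)) {
    stop("variable ", varname, " has no units attribute", call. = FALSE)
  }
  lat <- as.numeric(nc$dim[[d_lat]]$vals)
  lon <- as.numeric(nc$dim[[d_lon]]$vals)
  tvals <- as.numeric(nc$dim[[d_time]]$vals)
  tunits <- nc$dim[[d_time]]$units
  time <- parse_nc_time(tvals, tunits)
  if (!is_regular(lat) || !is_regular(lon)) {
    stop("irregular grid axes in ", path, call. = FALSE)
  }
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  # reorder to [time, lat, lon] using the variable's own dim order
  vdims <- vapply(v$dim, function(d) d$name, character(1))
  perm <- match(c(d_time, d_lat, d_lon), vdims)
  if (anyNA(perm)) stop("variable ", varname, " lacks time/lat/lon dims",
                        call. = FALSE)
  vals <- aperm(vals, perm)
  flip_lat <- length(lat) > 1L && lat[1L] > lat[2L]
  if (flip_lat) {
    lat <- rev(lat); vals <- vals[, rev(seq_along(lat)), , drop = FALSE]
  }
  if (grepl("^(K|kelvin)$", units, ignore.case = TRUE)) {
    vals <- vals - 273.15
    units <- "degC"
  }
  hourly_grid(lat, lon, time, vals, units = units, varname = varname)
}

parse_nc_time <- function(vals, units) {
  m <- regmatches(units, regexec(
    "^(seconds|hours|days) since ([0-9]{4}-[0-9]{2}-[0-9]{2})[ T]?([0-9:.]*)",
    units))[[1]]
  if (length(m) == 0L) stop("unsupported time units: ", units, call. = FALSE)
  origin <- as.POSIXct(paste(m[3], ifelse(nzchar(m[4]), m[4], "00:00:00")),
                       tz = "UTC")
  mult <- c(seconds = 1, hours = 3600, days = 86400)[[m[2]]]
  as.POSIXct(round(as.numeric(origin) + vals * mult),
             origin = "1970-01-01", tz = "UTC")
}

#' Write a region set to GeoJSON
#'
#' @param regions A [region_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  features <- lapply(seq_len(nrow(regions)), function(k) {
    rings <- lapply(regions$geometry[[k]], function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
    })
    list(type = "Feature",
         properties = list(region_id = regions$region_id[k],
                           level = regions$level[k]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region set from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features.  Unclosed rings are
#' repaired by closing them; duplicate identifiers or a missing
#' identifier attribute are errors.
#'
#' @param path GeoJSON file path.
#' @param id_field Name of the feature property holding the region
#'   identifier; default `"region_id"`.
#' @return A [region_set()].
#' @export
read_regions_file <- function(path, id_field = "region_id") {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  props1 <- names(fc$features[[1]]$properties)
  ids <- vapply(fc$features, function(f) {
    v <- f$properties[[id_field]]
    if (is.null(v)) {
      stop("id_field '", id_field, "' absent; available fields: ",
           paste(props1, collapse = ", "), call. = FALSE)
    }
    as.character(v)
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate region identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  level <- fc$features[[1]]$properties$level %||% "unknown"
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  geometry <- lapply(fc$features, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") {
      lapply(g$coordinates, ring_to_matrix)
    } else if (g$type == "MultiPolygon") {
      # flatten: exterior rings and holes of all parts
      unlist(lapply(g$coordinates, function(poly) {
        lapply(poly, ring_to_matrix)
      }), recursive = FALSE)
    } else {
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    }
  })
  region_set(ids, geometry, level = level)
}

#' Write a population grid to NetCDF
#'
#' @param population A [population_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_nc <- function(population, path) {
  stopifnot(inherits(population, "population_grid"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", population$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", population$lat)
  dim_epoch <- ncdf4::ncdim_def("epoch", "year",
                                as.double(population$epochs))
  var <- ncdf4::ncvar_def("population", "persons",
                          list(dim_lon, dim_lat, dim_epoch),
                          missval = -1, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, aperm(population$values, c(3L, 2L, 1L)))
  invisible(path)
}

#' Read a population grid from NetCDF
#'
#' @param path NetCDF file path with `lon`, `lat`, `epoch` dimensions and
#'   a `population` variable.
#' @return A [population_grid()].
#' @export
read_population_file <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  epochs <- as.integer(nc$dim$epoch$vals)
  vals <- ncdf4::ncvar_get(nc, "population", collapse_degen = FALSE)
  population_grid(lat, lon, epochs, aperm(vals, c(3L, 2L, 1L)))
}

#' Write one of the three output tables
#'
#' File names follow the schema `<dataset>_<spatiallevel>.csv` with
#' dataset prefixes `teedaily`, `teeyearly`, `teewave` (e.g.
#' `teewave_nuts2.csv`).  Dates are ISO 8601 and missing values empty
#' strings.
#'
#' @param table Non-empty data frame (daily, yearly or wave table).
#' @param dataset `"daily"`, `"yearly"` or `"wave"`.
#' @param level Spatial level label used in the file name (e.g.
#'   `"nuts2"`, `"synthetic"`).
#' @param outdir Output directory (created if needed).
#' @return The written file path.
#' @export
write_table <- function(table, dataset = c("daily", "yearly", "wave"),
                        level, outdir = ".") {
  dataset <- match.arg(dataset)
  if (is.null(table) || nrow(table) == 0L) {
    stop("refusing to write an empty ", dataset, " table", call. = FALSE)
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- file.path(outdir, sprintf("tee%s_%s.csv", dataset, level))
  readr::write_csv(table, path, na = "")
  path
}

#' Read back an output table
#'
#' @param path CSV path written by [write_table()].
#' @return A tibble with `date` columns parsed as `Date`.
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "")
}

#' Quality-control report over pipeline outputs
#'
#' Report-only checks (no errors): daily ordering
#' `t_min <= t_mean <= t_max` (also for population-weighted and
#' comfort-index triples), duplicate (region, date) / (region, year)
#' keys, yearly day counts within `[0, n]`, exceedance fractions in
#' `[0, 1]`, non-negative degree days, wave internal consistency
#' `n_days = end - start + 1`, and no wave longer than `max_wave_days`
#' (300: the canonical example of an unreasonable value).
#'
#' @param daily,yearly,waves Optional tables to check (at least one).
#' @param max_wave_days Upper sanity bound on wave length; default 300.
#' @return An object of class `qc_report`: a tibble of violations
#'   (zero rows = clean) with columns `table`, `check`, `n_violations`,
#'   `detail`.
#' @export
run_qc <- function(daily = NULL, yearly = NULL, waves = NULL,
                   max_wave_days = 300L) {
  if (is.null(daily) && is.null(yearly) && is.null(waves)) {
    stop("supply at least one table", call. = FALSE)
  }
  viol <- list()
  add <- function(tab, check, n, detail) {
    if (n > 0) {
      viol[[length(viol) + 1L]] <<- tibble::tibble(
        table = tab, check = check, n_violations = as.integer(n),
        detail = detail)
    }
  }
  if (!is.null(daily)) {
    for (pref in c("t", "t_pw", "utci")) {
      cols <- switch(pref,
                     t = c("t_min", "t_mean", "t_max"),
                     t_pw = c("t_min_pw", "t_mean_pw", "t_max_pw"),
                     utci = c("utci_min", "utci_mean", "utci_max"))
      if (!all(cols %in% names(daily))) next
      bad <- daily[[cols[1]]] > daily[[cols[2]]] |
        daily[[cols[2]]] > daily[[cols[3]]]
      add("daily", paste0("ordering_", pref), sum(bad, na.rm = TRUE),
          "min <= mean <= max violated")
    }
    add("daily", "duplicate_keys",
        sum(duplicated(daily[c("region_id", "date")])),
        "duplicate (region_id, date)")
  }
  if (!is.null(yearly)) {
    cnt_cols <- grep("^(days_above_|days_below_|tropical_nights|polar_days)",
                     names(yearly), value = TRUE)
    for (cc in cnt_cols) {
      bad <- yearly[[cc]] < 0 | yearly[[cc]] > yearly$n
      add("yearly", paste0("count_range_", cc), sum(bad, na.rm = TRUE),
          "day count outside [0, n]")
    }
    frac_cols <- grep("^expected_", names(yearly), value = TRUE)
    for (cc in frac_cols) {
      bad <- yearly[[cc]] < 0 | yearly[[cc]] > 1
      add("yearly", paste0("fraction_range_", cc), sum(bad, na.rm = TRUE),
          "fraction outside [0, 1]")
    }
    for (cc in intersect(c("cdd", "hdd"), names(yearly))) {
      add("yearly", paste0("negative_", cc),
          sum(yearly[[cc]] < 0, na.rm = TRUE), "negative degree days")
    }
    add("yearly", "duplicate_keys",
        sum(duplicated(yearly[c("region_id", "year")])),
        "duplicate (region_id, year)")
  }
  if (!is.null(waves)) {
    if (nrow(waves) > 0L) {
      bad_len <- waves$n_days !=
        as.integer(waves$end_date) - as.integer(waves$start_date) + 1L
      add("wave", "length_consistency", sum(bad_len, na.rm = TRUE),
          "n_days != end - start + 1")
      add("wave", "wave_too_long",
          sum(waves$n_days > max_wave_days, na.rm = TRUE),
          sprintf("wave longer than %d days", max_wave_days))
    }
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    tibble::tibble(table = character(0), check = character(0),
                   n_violations = integer(0), detail = character(0))
  class(out) <- c("qc_report", class(out))
  out
}

#' @export
print.qc_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<qc_report> clean: no violations\n")
  } else {
    cat(sprintf("<qc_report> %d violated check(s), %d record(s)\n",
                nrow(x), sum(x$n_violations)))
    print(tibble::as_tibble(x))
  }
  invisible(x)
}

#' Number of QC violations in a report
#' @param report A [run_qc()] result.
#' @return Integer total count of violating records.
#' @export
qc_violation_count <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  if (nrow(report) == 0L) 0L else sum(report$n_violations)
}

#' Machine-readable codebook for the yearly metrics table
#'
#' One row per output column: definition, units, and the formula variant
#' in force.  Emitted alongside the yearly CSV so every output file is
#' self-describing.
#'
#' @param heat_thresholds,cold_thresholds Absolute threshold sets (degC).
#' @param degree_day_variant `"standard"` or `"as_printed"`.
#' @param reference_years Reference window for percentiles/ECDF.
#' @return A tibble with columns `column`, `definition`, `units`.
#' @export
metric_codebook <- function(heat_thresholds = HEAT_THRESHOLDS,
                            cold_thresholds = COLD_THRESHOLDS,
                            degree_day_variant = "standard",
                            reference_years = c(1950, 1990)) {
  ref <- paste(reference_years, collapse = "-")
  dd <- if (degree_day_variant == "standard") {
    "daily midpoint (t_max + t_min)/2"
  } else "daily half-range (t_max - t_min)/2"
  rows <- list(
    c("region_id", "region identifier", ""),
    c("year", "calendar year", ""),
    c("n", "days in year", "days"),
    c("tropical_nights",
      sprintf("days with t_min > %g degC (strict)", TROPICAL_NIGHT_TMIN),
      "days"),
    c("polar_days",
      sprintf("days with t_max < %g degC (strict)", POLAR_DAY_TMAX), "days")
  )
  for (t in heat_thresholds) rows[[length(rows) + 1L]] <-
    c(paste0("days_above_", thr_label(t)),
      sprintf("days with t_mean > %g degC (strict)", t), "days")
  for (t in cold_thresholds) rows[[length(rows) + 1L]] <-
    c(paste0("days_below_", thr_label(t)),
      sprintf("days with t_mean < %g degC (strict)", t), "days")
  for (t in heat_thresholds) rows[[length(rows) + 1L]] <-
    c(paste0("expected_above_", thr_label(t)),
      sprintf("1 - F_n(%g): reference-period (%s) fraction of days > %g degC",
              t, ref, t), "unitless")
  for (t in cold_thresholds) rows[[length(rows) + 1L]] <-
    c(paste0("expected_below_", thr_label(t)),
      sprintf("F_n(%g): reference-period (%s) fraction of days <= %g degC",
              t, ref, t), "unitless")
  rows[[length(rows) + 1L]] <- c(
    "cdd", sprintf("cooling degree days: sum of (m - %g) over days with m > %g, m = %s",
                   CDD_BASE, CDD_BASE, dd), "degC")
  rows[[length(rows) + 1L]] <- c(
    "hdd", sprintf("heating degree days: sum of (%g - m) over days with m < %g, m = %s",
                   HDD_BASE, HDD_BASE, dd), "degC")
  for (p in UPPER_PERCENTILES) rows[[length(rows) + 1L]] <-
    c(paste0("days_above_", pct_label(p)),
      sprintf("days above the region's %s reference %gth percentile (strict)",
              ref, p * 100), "days")
  for (p in LOWER_PERCENTILES) rows[[length(rows) + 1L]] <-
    c(paste0("days_below_", pct_label(p)),
      sprintf("days below the region's %s reference %gth percentile (strict)",
              ref, p * 100), "days")
  for (p in sort(c(LOWER_PERCENTILES, UPPER_PERCENTILES)))
    rows[[length(rows) + 1L]] <-
    c(paste0("t_at_", pct_label(p)),
      sprintf("temperature at the region's %s reference %gth percentile (linear order-statistic interpolation)",
              ref, p * 100), "degC")
  m <- do.call(rbind, rows)
  tibble::tibble(column = m[, 1L], definition = m[, 2L], units = m[, 3L])
}

#' Write the codebook as JSON
#' @param codebook A [metric_codebook()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(codebook, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
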