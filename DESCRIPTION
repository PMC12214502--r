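Package: tempextremes
Title: Regional Extreme-Temperature Exposure Measures and Metrics from
    Gridded Hourly Climate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates gridded hourly temperature (and optionally
    thermal-comfort index) fields to daily region-level measures using
    equal-weight or population-weighted zonal means, computes a catalogue
    of yearly extreme-temperature metrics (tropical nights, polar days,
    days above/below absolute thresholds, expected exceedance fractions,
    cooling and heating degree days, reference-period percentile
    thresholds and percentile exceedance counts), and detects maximal
    runs of consecutive extreme days (heatwaves and coldsnaps).  Includes
    a synthetic-climate generator for fully reproducible pipelines,
    NetCDF/GeoJSON/CSV input and output, quality-control checks, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ncdf4,
    readr,
    sp,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
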