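---
title: "Methods: regional extreme-temperature measures, metrics and waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional extreme-temperature measures, metrics and waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological and demographic studies of temperature-related outcomes
need exposure summaries on the spatial units that health and population
statistics are published on (administrative regions such as NUTS 2/3),
not on the fine lon/lat grids that reanalysis products ship.
`tempextremes` turns gridded hourly temperature fields into three
region-level products:

* a **daily table** of regional minimum, maximum and mean temperature
  (optionally population-weighted, optionally for a thermal-comfort
  index as a second stream),
* a **yearly table** with a catalogue of extreme-temperature metrics,
* a **wave table** of maximal runs of consecutive extreme days
  (heatwaves and coldsnaps) with start date, end date and length.

## Daily measures

A grid cell belongs to a region iff its **center** lies inside the
region polygon.  The source statement for this pipeline family is that
cells falling across a region are averaged with equal weights; it does
not pin down an inclusion rule, so the center rule is this package's
documented choice: it is deterministic, it partitions the cells (no
cell counted twice), and it is consistent with equal weighting — no
fractional area weights, and no latitude-cosine correction.  A center
exactly on a shared boundary goes to the lexicographically smallest
`region_id`, for bit-reproducibility across platforms.  Regions that
capture no valid cell center (e.g. islands smaller than a cell) yield
missing measures and a warning.

For each hour, the regional value is the equal-weight mean over the
region's unmasked cells.  The daily minimum, maximum and mean are then
the extremes and average of the (up to 24) regional hourly values of the
UTC calendar date.  The order matters for the extremes: averaging
per-cell daily minima would give a systematically lower "minimum" than
the minimum of the regional series.  We collapse the regional hourly
series because the daily measures are defined from the hourly values
*for the region*; this is a documented design choice, asserted by a
regression test with two cells in opposite phase.  Day boundaries are
UTC, the native convention of reanalysis time stamps; no local-solar-time
correction is applied (a known limitation at continental longitudinal
span).

Population weighting replaces the equal weights by population counts:
`sum(w_i x_i) / sum(w_i)`.  Population products are released at
multi-year epochs; each calendar year uses the most recent epoch **not
later** than the year (2004 uses 2000; 2006 uses 2005), never a future
epoch, so rapid population change is not projected backwards.  Years
before the first epoch get missing population-weighted columns.  Because
population is an extensive quantity, a finer population raster is
aggregated (summed) onto each climate cell footprint by
nearest-neighbour before weighting.  A region whose total weight is zero
yields missing values and a logged warning.

## Yearly metrics

All metrics are computed per region and complete calendar year from the
daily table (partial years at the series edges are dropped with a
warning, not extrapolated).  All inequalities are **strict**, matching
the indicator definitions of the metric catalogue.

* **Tropical nights**: days with `t_min > 20` °C.  **Polar days**: days
  with `t_max < 10` °C.
* **Days above/below absolute thresholds** on the daily mean: above
  {20, 25, 30, 35, 40, 45} °C, below {−20, −15, −10, −5, 0, 5} °C.
* **Expected days above/below**: `1 − F_n(t)` and `F_n(t)` where `F_n`
  is the empirical CDF (fraction of observations ≤ t).  The observation
  set behind `F_n` is not fixed by the source description; the default
  here is the same historical reference window as the percentile
  thresholds, with a `focal` option that uses the focal year instead
  (which makes the metric a rescaled day count).  The values are
  reported as unitless fractions, exactly as the defining formulas
  produce them, not multiplied by 365.
* **Cooling/heating degree days**: sums of degrees by which a daily
  temperature summary `m` exceeds 24 °C (CDD) or falls below 20 °C
  (HDD).  The catalogue's printed formula uses the half-range
  `(t_max − t_min)/2` for `m`, which is dimensionally a spread, not a
  temperature, and is inconsistent with the accompanying prose ("degrees
  each daily temperature is above a threshold").  The default is
  therefore the conventional daily midpoint `(t_max + t_min)/2`
  (`formula_variant = "standard"`), and `"as_printed"` reproduces the
  half-range literally.  Both variants are tested; the variant in force
  is recorded in the codebook and log.  Days with midpoint in
  [20, 24] °C contribute to neither sum.
* **Percentile thresholds and exceedances**: per-region empirical
  quantiles `t(p, j)` at p ∈ {0.01, 0.05, 0.10, 0.90, 0.95, 0.99} over a
  historical reference window (default 1950–1990, configurable), pooling
  all calendar days — not day-of-year windows; pooling follows the
  source's description, though many climatological conventions differ.
  Quantiles use linear interpolation between order statistics (R type 7,
  the common default of mainstream numerical environments); the choice
  is recorded in output metadata.  The catalogue lists the daily maximum
  for the percentile-day metrics while the accompanying text derives the
  percentiles from the daily mean; the default here is the daily mean,
  configurable to `t_max`.

## Waves

A wave is a **maximal run of at least two consecutive extreme days** for
one region and one threshold.  Twelve default wave types: heatwaves
above 20/30/40 °C and above the 90th/95th/99th percentiles, coldsnaps
below 10/0/−10 °C and below the 10th/5th/1st percentiles.  Percentile
waves reuse the same `t(p, j)` table as the yearly metrics (single
source of truth).  The daily measure for waves is `t_mean` by default
(consistent with the absolute-threshold yearly metrics; the source does
not name the measure) and is configurable.  Runs are detected over each
region's full contiguous series, not reset at year ends, so winter
coldsnaps may straddle New Year; gaps in the date sequence are an error
because runs are undefined across them.  Emitting every run of length
≥ 2 gives users the largest possible choice: filtering the table to
`n_days >= L` is provably identical to re-detecting with a minimum
length of `L` (tested).  A missing daily value breaks a run: a day that
cannot be certified extreme is treated as not extreme.

## Synthetic data

The generator exists so every stage is testable without downloads.  The
hourly field at a cell is

```
baseline + seasonal sinusoid (period 1 yr, peak mid-July)
         + diurnal sinusoid (period 24 h, peak 15:00 UTC)
         + linear latitude gradient
         + stationary AR(1) noise (per cell, independent across cells)
```

with a static random "ocean" mask.  Defaults describe a mid-latitude
temperate climate: baseline 11 °C, seasonal half-amplitude 10 °C,
diurnal half-amplitude 4 °C, noise with 3 °C marginal standard
deviation and hourly lag-1 autocorrelation 0.95, gradient −0.6 °C per
degree latitude, 10 % masked cells.  The AR(1) persistence is the one
structurally important choice: without temporal correlation,
consecutive-day exceedances (waves) would be vanishingly rare and the
run detector untested at realistic event rates.  Regions are recursive
bisections of the extent (exact proportional splits by default, hence
quadrants for four regions on a square; a `jitter` argument randomises
layouts for oracle tests).  Population is a smooth log-Gaussian surface
per epoch with strong epoch-to-epoch correlation, or exactly uniform on
request (the degenerate case in which weighted and unweighted measures
must coincide exactly).

What the generator does **not** emulate: weather fronts and spatially
correlated anomalies, humidity/wind/radiation (the comfort-index stream
is just a second temperature-like field at coarser resolution), trends
and non-stationarity, and the skewed tails of real temperature
distributions.  Passing tests therefore demonstrate the correctness of
the aggregation, counting and run-detection logic under known
conditions — not the climatological fidelity of any real-data product.

## Numerical and interface choices

* Strict inequalities everywhere; values exactly at a threshold never
  count (so a constant 25 °C year has zero days above 25 °C).
* Quantiles: type 7; ECDF: inclusive `≤`.
* Missing hours are excluded from daily statistics; a date with no
  valid hour has missing measures.
* Output CSVs follow the `dataset_spatiallevel.csv` schema
  (`teedaily_`, `teeyearly_`, `teewave_` prefixes), ISO 8601 dates,
  empty strings for missing values; a JSON codebook documents every
  yearly column and the formula variant in force; a plain-text log
  records every constant actually used, so any output is reproducible
  from its log and config.
* CSV round-trips preserve integers and strings exactly and reals to
  within one unit in the last place (the reader's float parser may
  differ in the final bit), which is why stage-by-stage and one-shot
  runs are compared at 1e-12 rather than byte-for-byte.
* Problem sizes used by the shipped checks: unit tests run on grids of
  tens of cells and single years; the end-to-end check uses a
  10° × 10° extent at 0.5° (400 cells), 45 years of hourly data and 4
  regions, which exercises the memory-lean per-cell generation path;
  oracle checks use 20 random layouts, 500 random region-years and
  1,000 random boolean series.

## Known limitations

* Center-rule cell inclusion differs from exact-area overlap weighting;
  for regions small relative to a cell the measures are missing rather
  than interpolated.
* UTC day boundaries shift the nominal "day" by up to several hours of
  local solar time at the extent's edges.
* No bias correction, gap filling, or trend adjustment.
* GeoJSON is the supported region format; geometry validation repairs
  unclosed rings but does not attempt full topology repair.
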