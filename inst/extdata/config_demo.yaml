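# Demonstration configuration: a compact synthetic domain whose daily
# series covers the default 1950-1990 percentile reference window.
# Every omitted key falls back to the package defaults
# (see default_config()).
level: synthetic
outdir: tee_output
seed: 1
synthetic:
  extent: [0.0, 5.0, 45.0, 50.0]
  resolution: 1.0
  start_date: "1950-01-01"
  end_date: "1995-12-31"
  n_regions: 4
  climate:
    baseline_mean: 11
    seasonal_amplitude: 10
    diurnal_amplitude: 4
    noise_sd: 3
    noise_autocorr: 0.95
    spatial_gradient: -0.6
    missing_fraction: 0.1
  population:
    enabled: true
    resolution: 0.5
    epochs: [1990, 1995, 2000, 2005, 2010, 2015, 2020]
metrics:
  reference_years: [1950, 1990]
  degree_day_variant: standard
waves:
  min_length: 2
  measure: t_mean
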