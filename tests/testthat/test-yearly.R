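test_that("threshold day counts use strict inequalities", {
  x <- rep(25, 365)
  spec20 <- threshold_spec("t_mean", "above", "absolute", 20)
  spec25 <- threshold_spec("t_mean", "above", "absolute", 25)
  expect_equal(count_threshold_days(x, spec20), 365)
  expect_equal(count_threshold_days(x, spec25), 0)  # strict at the boundary
  below <- threshold_spec("t_mean", "below", "absolute", 30)
  expect_equal(count_threshold_days(x, below), 365)
})

test_that("threshold day counts match a day-by-day loop on random series", {
  set.seed(20)
  for (k in 1:50) {
    x <- rnorm(365, mean = runif(1, -5, 25), sd = runif(1, 1, 8))
    t <- runif(1, -10, 30)
    up <- threshold_spec("t_mean", "above", "absolute", t)
    dn <- threshold_spec("t_mean", "below", "absolute", t)
    n_up <- 0L; n_dn <- 0L
    for (v in x) {
      if (v > t) n_up <- n_up + 1L
      if (v < t) n_dn <- n_dn + 1L
    }
    expect_identical(count_threshold_days(x, up), n_up)
    expect_identical(count_threshold_days(x, dn), n_dn)
  }
})

test_that("percentile specs require and use the thresholds table", {
  d <- make_year_daily("A", 1981, seq(-10, 25, length.out = 365))
  th <- percentile_thresholds(d, reference_years = c(1981, 1981))
  spec <- threshold_spec("t_mean", "above", "percentile", 0.95)
  expect_error(count_threshold_days(d$t_mean, spec), "requires")
  expect_error(count_threshold_days(d$t_mean, spec, th, "nope"),
               "no percentile threshold")
  n <- count_threshold_days(d$t_mean, spec, th, "A")
  expect_equal(n, sum(d$t_mean > th$value[th$region_id == "A" &
                                            th$p == 0.95]))
})

test_that("ecdf_fraction is the inclusive fraction at or below t", {
  expect_equal(ecdf_fraction(c(-5, 0, 5, 10), 0), 0.5)
  expect_equal(ecdf_fraction(c(-5, 0, 5, 10), -6), 0)
  expect_equal(ecdf_fraction(c(-5, 0, 5, 10), 10), 1)
  expect_error(ecdf_fraction(numeric(0), 0), "empty reference")
  # complementarity of the expected-days formulas at any threshold
  set.seed(4)
  ref <- rnorm(500, 8, 6)
  for (t in c(-20, -5, 0, 8, 25, 45)) {
    expect_equal((1 - ecdf_fraction(ref, t)) + ecdf_fraction(ref, t), 1)
  }
})

test_that("degree days evaluate both formula variants correctly", {
  # midpoint 26 -> 2 cooling degree days
  expect_equal(degree_days(30, 22, "cooling"), 2)
  # midpoint exactly at the base contributes nothing (strict inequality)
  expect_equal(degree_days(26, 22, "cooling"), 0)
  # midpoint 15 -> 5 heating degree days
  expect_equal(degree_days(20, 10, "heating"), 5)
  # as-printed variant uses the half-range: (30 - 22)/2 = 4 -> HDD 16
  expect_equal(degree_days(30, 22, "heating", "as_printed"), 16)
  expect_equal(degree_days(30, 22, "heating", "standard"), 0)
  expect_error(degree_days(10, 20, "cooling"), "t_min > t_max")
  # dead zone: days with midpoint in [20, 24] affect neither CDD nor HDD
  tmax <- c(30, 23); tmin <- c(26, 21)   # midpoints 28, 22
  expect_equal(degree_days(tmax, tmin, "cooling"),
               degree_days(30, 26, "cooling"))
  expect_equal(degree_days(tmax, tmin, "heating"), 0)
})

test_that("percentile thresholds follow type-7 order-statistic interpolation", {
  d <- make_year_daily("A", 1981, seq(-10, 25, length.out = 365))
  d$t_mean <- c(1:100, rep(50, 265))  # known reference values
  dsub <- d[1:100, ]
  dsub$date <- seq(as.Date("1981-01-01"), by = "day", length.out = 100)
  th <- percentile_thresholds(dsub, percentiles = c(0.1, 0.9),
                              reference_years = c(1981, 1981))
  expect_equal(th$value[th$p == 0.9], 1 + 0.9 * 99)   # 90.1
  expect_equal(th$value[th$p == 0.1], 1 + 0.1 * 99)

  # constant reference collapses every percentile onto the constant
  dc <- make_year_daily("A", 1981, rep(7, 365))
  thc <- percentile_thresholds(dc, reference_years = c(1981, 1981))
  expect_true(all(thc$value == 7))

  # monotone in p for every region
  dd <- rbind(make_year_daily("A", 1981, rnorm(365, 10, 5)),
              make_year_daily("B", 1981, rnorm(365, 5, 8)))
  thm <- percentile_thresholds(dd, reference_years = c(1981, 1981))
  for (id in c("A", "B")) {
    v <- thm$value[thm$region_id == id][order(thm$p[thm$region_id == id])]
    expect_true(all(diff(v) >= 0))
  }
  expect_error(percentile_thresholds(dd, reference_years = c(1800, 1801)),
               "no reference-period data")
})

test_that("a constant 25 degC year reproduces its closed-form metrics", {
  d <- make_year_daily("A", 1981, rep(25, 365), spread = 0)
  th <- percentile_thresholds(d, reference_years = c(1981, 1981))
  y <- build_yearly_table(d, th)
  expect_equal(y$n, 365)
  expect_equal(y$days_above_20, 365)
  expect_equal(y$days_above_25, 0)
  expect_equal(y$cdd, 365)   # midpoint 25 -> 1 degC per day
  expect_equal(y$hdd, 0)
  expect_equal(y$tropical_nights, 365)
  expect_equal(y$polar_days, 0)
  expect_true(all(y[grep("^t_at_", names(y))] == 25))
})

test_that("yearly metric columns agree with the single-metric operations", {
  set.seed(31)
  d <- make_year_daily("A", 1982, rnorm(365, 12, 9))
  th <- percentile_thresholds(d, reference_years = c(1982, 1982))
  y <- build_yearly_table(d, th)
  expect_equal(y$days_above_30,
               count_threshold_days(d$t_mean,
                                    threshold_spec("t_mean", "above",
                                                   "absolute", 30)))
  expect_equal(y$days_below_0,
               count_threshold_days(d$t_mean,
                                    threshold_spec("t_mean", "below",
                                                   "absolute", 0)))
  expect_equal(y$cdd, degree_days(d$t_max, d$t_min, "cooling"))
  expect_equal(y$hdd, degree_days(d$t_max, d$t_min, "heating"))
  expect_equal(y$expected_below_0, ecdf_fraction(d$t_mean, 0))
  expect_equal(y$days_above_p95,
               count_threshold_days(d$t_mean,
                                    threshold_spec("t_mean", "above",
                                                   "percentile", 0.95),
                                    th, "A"))
})

test_that("day-count families are monotone in their thresholds", {
  set.seed(12)
  d <- make_year_daily("A", 1983, rnorm(365, 8, 12))
  th <- percentile_thresholds(d, reference_years = c(1983, 1983))
  y <- build_yearly_table(d, th)
  above <- unlist(y[paste0("days_above_", c(20, 25, 30, 35, 40, 45))])
  expect_true(all(diff(above) <= 0))
  below <- unlist(y[paste0("days_below_", c("m20", "m15", "m10", "m5",
                                            "0", "5"))])
  expect_true(all(diff(below) >= 0))
  pa <- unlist(y[paste0("days_above_", c("p90", "p95", "p99"))])
  expect_true(all(diff(pa) <= 0))
  pb <- unlist(y[paste0("days_below_", c("p01", "p05", "p10"))])
  expect_true(all(diff(pb) >= 0))
  # complementarity: above(t) + below(t) + equal(t) = n
  t <- 8
  expect_equal(sum(d$t_mean > t) + sum(d$t_mean < t) + sum(d$t_mean == t),
               y$n)
})

test_that("partial years are dropped with a warning and leap years keep 366 days", {
  d <- rbind(make_year_daily("A", 1983, rnorm(365, 10, 5)),
             make_year_daily("A", 1984, rnorm(366, 10, 5)))
  half <- d[1:500, ]   # truncates 1984
  th <- percentile_thresholds(d, reference_years = c(1983, 1984))
  expect_warning(y <- build_yearly_table(half, th), "partial year 1984")
  expect_equal(y$year, 1983)
  y2 <- build_yearly_table(d, th)
  expect_equal(y2$n[y2$year == 1984], 366)
})

test_that("percentile thresholds applied back to their reference flag ~p*n days", {
  set.seed(17)
  dates <- seq(as.Date("1950-01-01"), as.Date("1990-12-31"), by = "day")
  x <- rnorm(length(dates), 10, 7)
  d <- tibble::tibble(region_id = "A", date = dates,
                      t_min = x - 5, t_max = x + 5, t_mean = x)
  th <- percentile_thresholds(d, reference_years = c(1950, 1990))
  n <- sum(!is.na(d$t_mean))
  for (p in c(0.05, 0.95)) {
    cut <- th$value[abs(th$p - p) < 1e-9]
    expect_equal(sum(d$t_mean < cut) / n, p, tolerance = 0.01)
  }
})
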