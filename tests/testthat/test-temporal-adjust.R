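hourly_fixture <- function(daily_values, missing_hours = list()) {
  days <- seq(as.Date("2016-01-01"), by = "day", length.out = length(daily_values))
  ts <- as.POSIXct(rep(days, each = 24), tz = "UTC") + rep(0:23, length(days)) * 3600
  v <- rep(daily_values, each = 24)
  for (i in seq_along(missing_hours)) {
    if (length(missing_hours[[i]])) {
      v[(i - 1) * 24 + missing_hours[[i]]] <- NA_real_
    }
  }
  list(timestamps = ts, values = v)
}

test_that("daily reduction applies the strict >25% completeness rule", {
  f <- hourly_fixture(c(10, 10, 10))
  d <- daily_from_hourly(f$timestamps, f$values)
  expect_equal(d$value, c(10, 10, 10))
  expect_false(any(d$filled))

  # exactly 6 of 24 present (25%): gap-filled, not averaged
  f6 <- hourly_fixture(c(10, 99, 20), missing_hours = list(integer(0), 7:24, integer(0)))
  d6 <- daily_from_hourly(f6$timestamps, f6$values)
  expect_true(d6$filled[2])
  expect_equal(d6$value[2], 15) # mean of flanking 10 and 20, not 99

  # 7 of 24 present (> 25%): averaged from what is there
  f7 <- hourly_fixture(c(10, 99, 20), missing_hours = list(integer(0), 8:24, integer(0)))
  d7 <- daily_from_hourly(f7$timestamps, f7$values)
  expect_false(d7$filled[2])
  expect_equal(d7$value[2], 99)

  # one-sided fill at the series ends
  fe <- hourly_fixture(c(99, 10, 20), missing_hours = list(1:24, integer(0), integer(0)))
  de <- daily_from_hourly(fe$timestamps, fe$values)
  expect_equal(de$value[1], 10)

  expect_error(
    daily_from_hourly(f$timestamps, rep(NA_real_, length(f$values))),
    class = "lur_temporal_error"
  )
})

test_that("PM2.5 is half of PM10, elementwise and in the mean", {
  expect_equal(estimate_pm25(24.9), 12.45)
  expect_equal(estimate_pm25(0), 0)
  x <- data.frame(date = as.Date("2016-01-01") + 0:9, value = seq(2, 38, by = 4))
  y <- estimate_pm25(x)
  expect_equal(y$value, x$value / 2)
  expect_equal(mean(y$value), 0.5 * mean(x$value))
})

test_that("the NO2 gap-fill regression recovers noiseless coefficients and applies the preset", {
  set.seed(11)
  pm10 <- stats::runif(60, 10, 50)
  solar <- stats::runif(60, 0, 600)
  no2 <- 17.35 + 1.0 * pm10 - 0.07 * solar
  m <- fit_gap_fill(no2, pm10, solar)
  expect_equal(m$intercept, 17.35, tolerance = 1e-8)
  expect_equal(m$pm10_coef, 1.0, tolerance = 1e-8)
  expect_equal(m$solar_coef, -0.07, tolerance = 1e-8)
  expect_equal(m$fit_correlation, 1, tolerance = 1e-8)

  # the published preset evaluated by hand: 17.35 + 20 - 7
  expect_equal(apply_gap_fill(gap_fill_preset(), 20, 100), 30.35)

  expect_error(fit_gap_fill(no2[1:10], pm10[1:10], solar[1:10]), class = "lur_gapfill_error")
  expect_error(fit_gap_fill(no2, pm10, rep(100, 60)), class = "lur_gapfill_error")
})

test_that("gap-fill coefficient bias shrinks with sample size (Monte-Carlo consistency)", {
  bias_at <- function(n, seeds) {
    err <- vapply(seeds, function(s) {
      set.seed(s)
      pm10 <- stats::runif(n, 10, 50)
      solar <- stats::runif(n, 0, 600)
      no2 <- 17.35 + pm10 - 0.07 * solar + stats::rnorm(n, 0, 5)
      m <- fit_gap_fill(no2, pm10, solar)
      abs(m$pm10_coef - 1)
    }, numeric(1))
    mean(err)
  }
  seeds <- 1:20
  expect_lt(bias_at(5000, seeds), bias_at(50, seeds))
})

test_that("temporal adjustment subtracts the weekly-minus-seasonal correction and clamps at zero", {
  days <- seq(as.Date("2016-06-06"), as.Date("2016-09-25"), by = "day")
  ref <- data.frame(date = days, value = rep(25, length(days)))
  ref$value[days >= as.Date("2016-07-04") & days <= as.Date("2016-07-10")] <- 30
  # seasonal mean is slightly above 25 because of the elevated week
  season_mean <- mean(ref$value)
  windows <- list(warm = as.Date(c("2015-11-02", "2016-03-27")), cold = as.Date(c("2016-06-06", "2016-09-25")))

  rec <- data.frame(
    site_id = "S1", pollutant = "no2", season = "cold",
    start_date = as.Date("2016-07-04"), end_date = as.Date("2016-07-10"),
    value_ugm3 = 18
  )
  adj <- adjust_measurements(rec, ref, windows)
  expect_equal(adj$correction, 30 - season_mean)
  expect_equal(adj$adjusted_ugm3, 18 - (30 - season_mean))
  expect_false(adj$clamped)

  # negative adjusted value clamps to exactly 0 with the flag set
  rec$value_ugm3 <- 2
  ref2 <- ref
  ref2$value[days >= as.Date("2016-07-04") & days <= as.Date("2016-07-10")] <- 25 + 5 * length(days) / (length(days) - 7) # cf ~ 5
  adj2 <- adjust_measurements(rec, ref2, windows)
  expect_true(adj2$clamped)
  expect_identical(adj2$adjusted_ugm3, 0)

  # a measurement week equal to the seasonal mean gets cf = 0
  ref3 <- data.frame(date = days, value = rep(25, length(days)))
  rec$value_ugm3 <- 18
  adj3 <- adjust_measurements(rec, ref3, windows)
  expect_equal(adj3$correction, 0)
  expect_equal(adj3$adjusted_ugm3, 18)

  # week outside the season window is a typed error
  bad <- rec
  bad$start_date <- as.Date("2016-05-01")
  bad$end_date <- as.Date("2016-05-07")
  expect_error(adjust_measurements(bad, ref, windows), class = "lur_adjust_error")
})

test_that("seasonal and annual means follow the season-first averaging rule", {
  adj <- data.frame(
    site_id = c("S1", "S1", "S1", "S2"),
    pollutant = "no2",
    season = c("warm", "warm", "cold", "warm"),
    adjusted_ugm3 = c(15, 17, 27.9, 5),
    clamped = c(FALSE, FALSE, FALSE, TRUE)
  )
  sm <- seasonal_means(adj)
  s1 <- sm[sm$site_id == "S1", ]
  expect_equal(s1$value_ugm3[s1$season == "warm"], 16.0)
  expect_equal(s1$value_ugm3[s1$season == "cold"], 27.9)
  expect_equal(s1$value_ugm3[s1$season == "annual"], (16.0 + 27.9) / 2)
  expect_equal(s1$n_weeks[s1$season == "warm"], 2)
  # single-season site: annual equals the one available seasonal mean
  s2 <- sm[sm$site_id == "S2", ]
  expect_equal(s2$value_ugm3[s2$season == "annual"], 5)
  expect_true(all(s2$clamped))
})

test_that("under the parallel-series model the adjusted mean is week-invariant", {
  days <- seq(as.Date("2016-06-06"), as.Date("2016-09-25"), by = "day")
  set.seed(5)
  ref <- data.frame(date = days, value = 25 + cumsum(stats::rnorm(length(days), 0, 1)))
  windows <- list(warm = as.Date(c("2015-11-02", "2016-03-27")), cold = as.Date(c("2016-06-06", "2016-09-25")))
  offset <- 7.3
  week_starts <- seq(days[1], days[length(days)] - 6, by = "7 days")
  adj_values <- vapply(seq_along(week_starts), function(i) {
    ws <- week_starts[i]
    wk <- ref$date >= ws & ref$date <= ws + 6
    rec <- data.frame(
      site_id = "S1", pollutant = "no2", season = "cold",
      start_date = ws, end_date = ws + 6,
      value_ugm3 = offset + mean(ref$value[wk])
    )
    adjust_measurements(rec, ref, windows)$adjusted_ugm3
  }, numeric(1))
  expect_equal(max(adj_values) - min(adj_values), 0, tolerance = 1e-9)
  expect_equal(adj_values[1], offset + mean(ref$value), tolerance = 1e-9)
})

test_that("noiseless synthetic studies are recovered exactly by the adjustment pipeline", {
  cfg <- tiny_config(noise_sd = 0, ref_gap_fraction = 0, lost_fraction = 0)
  st <- synthetic_study(cfg)
  for (poll in c("no2", "pm25")) {
    adj <- adjust_measurements(
      st$measurements[st$measurements$pollutant == poll, ],
      st$ref_daily[[poll]], cfg$season_windows
    )
    sm <- seasonal_means(adj)
    tm <- st$truth$true_site_means
    for (season in c("warm", "cold", "annual")) {
      sub <- sm[sm$season == season, ]
      expect_equal(
        sub$value_ugm3,
        tm[[season]][match(sub$site_id, tm$site_id)],
        tolerance = 1e-9
      )
    }
  }
})

test_that("daily NO2 gaps are filled from the fitted PM10 + solar model", {
  dates <- as.Date("2016-01-01") + 0:59
  set.seed(21)
  pm10 <- data.frame(date = dates, value = stats::runif(60, 10, 50))
  solar <- data.frame(date = dates, value = stats::runif(60, 0, 600))
  truth <- 17.35 + pm10$value - 0.07 * solar$value
  no2 <- data.frame(date = dates, value = truth)
  no2$value[41:60] <- NA # the post-cut-over stretch
  m <- fit_gap_fill(no2$value, pm10$value, solar$value)
  filled <- fill_no2_daily(no2, m, pm10, solar)
  expect_equal(filled$value, truth, tolerance = 1e-8)
  expect_identical(filled$gap_filled, c(rep(FALSE, 40), rep(TRUE, 20)))
})
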