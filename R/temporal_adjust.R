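# Temporal adjustment of asynchronous weekly measurements against a
# continuously operating reference monitor. Working resolution is the
# daily mean: hourly records are reduced to daily means under a
# completeness rule, short gaps are filled from neighbouring days, PM2.5
# is estimated as half of PM10, NO2 gaps are filled from a PM10 + solar
# regression, and each weekly measurement is corrected by the difference
# between the reference's week mean and its seasonal mean.

#' Reduce an hourly series to daily means with gap filling
#'
#' A daily mean is computed from the available hourly values when strictly
#' more than `min_frac` of the day's 24 slots are present (the default
#' reads "more than 25%" literally: 7+ of 24). Days failing the rule are
#' filled with the mean of the nearest previous and next qualifying daily
#' values (one-sided at the ends of the series).
#'
#' @param timestamps POSIXct hourly timestamps (UTC recommended).
#' @param values hourly values, `NA` for gaps.
#' @param min_frac completeness threshold as a fraction of 24 (strict `>`).
#' @return data frame `date, value, filled` covering every day from first
#'   to last timestamp.
#' @export
daily_from_hourly <- function(timestamps, values, min_frac = 0.25) {
  if (all(is.na(values))) {
    abort_lur("lur_temporal_error", "hourly series is entirely missing")
  }
  dates <- as.Date(timestamps, tz = "UTC")
  all_days <- seq(min(dates), max(dates), by = "day")
  idx <- match(dates, all_days)
  n_avail <- tabulate(idx[!is.na(values)], nbins = length(all_days))
  sums <- rep(0, length(all_days))
  ok <- !is.na(values)
  sums[sort(unique(idx[ok]))] <- vapply(
    split(values[ok], idx[ok]), sum, numeric(1)
  )
  daily <- ifelse(n_avail > min_frac * 24, sums / n_avail, NA_real_)
  filled <- is.na(daily)
  if (any(filled)) {
    avail_idx <- which(!filled)
    if (length(avail_idx) == 0L) {
      abort_lur("lur_temporal_error", "no day passes the completeness rule")
    }
    for (i in which(filled)) {
      prev <- avail_idx[avail_idx < i]
      nxt <- avail_idx[avail_idx > i]
      neigh <- c(
        if (length(prev)) daily[max(prev)],
        if (length(nxt)) daily[min(nxt)]
      )
      daily[i] <- mean(neigh)
    }
  }
  data.frame(date = all_days, value = daily, filled = filled)
}

#' Estimate daily PM2.5 from daily PM10
#'
#' Applies the literature rule PM2.5 = 0.5 * PM10, elementwise.
#'
#' @param daily_pm10 data frame `date, value` (or a numeric vector).
#' @return same shape with halved values.
#' @export
estimate_pm25 <- function(daily_pm10) {
  if (is.numeric(daily_pm10)) {
    return(0.5 * daily_pm10)
  }
  out <- daily_pm10
  out$value <- 0.5 * out$value
  out
}

#' Fit the NO2 gap-fill regression on PM10 and solar radiation
#'
#' Ordinary least squares of daily NO2 on daily PM10 and daily solar
#' radiation over their overlap, reporting the Pearson correlation between
#' fitted and observed values on the training days.
#'
#' @param daily_no2,daily_pm10,daily_solar aligned numeric vectors of daily
#'   means (`NA` allowed; complete cases are used).
#' @param min_days minimum overlapping days required.
#' @return a `gap_fill_model`: intercept (ug/m3), pm10_coef, solar_coef
#'   (ug/m3 per W/m2), fit_correlation, n.
#' @export
fit_gap_fill <- function(daily_no2, daily_pm10, daily_solar, min_days = 30) {
  ok <- stats::complete.cases(daily_no2, daily_pm10, daily_solar)
  if (sum(ok) < min_days) {
    abort_lur("lur_gapfill_error", "only %d overlapping days (< %d)", sum(ok), min_days)
  }
  if (stats::sd(daily_pm10[ok]) == 0 || stats::sd(daily_solar[ok]) == 0) {
    abort_lur("lur_gapfill_error", "a regressor is constant over the training overlap")
  }
  fit <- stats::lm(no2 ~ pm10 + solar, data = data.frame(
    no2 = daily_no2[ok], pm10 = daily_pm10[ok], solar = daily_solar[ok]
  ))
  if (any(is.na(stats::coef(fit)))) {
    abort_lur("lur_gapfill_error", "rank-deficient gap-fill design")
  }
  cf <- stats::coef(fit)
  structure(
    list(
      intercept = unname(cf[1]), pm10_coef = unname(cf[2]), solar_coef = unname(cf[3]),
      fit_correlation = stats::cor(stats::fitted(fit), daily_no2[ok]), n = sum(ok)
    ),
    class = "gap_fill_model"
  )
}

#' The published reference-station NO2 gap-fill model
#'
#' Shipped as a named preset for reproduction runs:
#' NO2 = 17.35 + 1.0 * PM10 - 0.07 * solar, training correlation 0.82.
#' These coefficients are specific to one station; fit your own with
#' [fit_gap_fill()] for any other reference site.
#'
#' @return a `gap_fill_model`.
#' @export
gap_fill_preset <- function() {
  structure(
    list(
      intercept = 17.35, pm10_coef = 1.0, solar_coef = -0.07,
      fit_correlation = 0.82, n = NA_integer_
    ),
    class = "gap_fill_model"
  )
}

#' @export
print.gap_fill_model <- function(x, ...) {
  cat(sprintf(
    "<gap_fill_model> NO2 = %.4g + %.4g*PM10 %+.4g*solar (r = %.2f, n = %s)\n",
    x$intercept, x$pm10_coef, x$solar_coef, x$fit_correlation, x$n
  ))
  invisible(x)
}

#' Predict NO2 from a gap-fill model
#'
#' @param model a `gap_fill_model`.
#' @param pm10,solar numeric vectors of daily means.
#' @return predicted daily NO2, ug/m3.
#' @export
apply_gap_fill <- function(model, pm10, solar) {
  stopifnot(inherits(model, "gap_fill_model"))
  model$intercept + model$pm10_coef * pm10 + model$solar_coef * solar
}

#' Fill missing daily NO2 values from PM10 and solar
#'
#' @param daily_no2 data frame `date, value` with `NA` gaps.
#' @param model a `gap_fill_model`.
#' @param daily_pm10,daily_solar data frames aligned by date.
#' @return `daily_no2` with gaps replaced and a `gap_filled` flag column.
#' @export
fill_no2_daily <- function(daily_no2, model, daily_pm10, daily_solar) {
  miss <- is.na(daily_no2$value)
  out <- daily_no2
  out$gap_filled <- miss
  if (any(miss)) {
    pm <- daily_pm10$value[match(out$date[miss], daily_pm10$date)]
    so <- daily_solar$value[match(out$date[miss], daily_solar$date)]
    out$value[miss] <- apply_gap_fill(model, pm, so)
  }
  out
}

#' Temporally adjust weekly measurements to a reference monitor
#'
#' For each record, the correction factor is the reference's daily-mean
#' average over the measurement week minus its average over the record's
#' season window; the factor is subtracted from the measured value and
#' negative results are clamped to 0 with a flag.
#'
#' @param records measurement table (`site_id, pollutant, season,
#'   start_date, end_date, value_ugm3`).
#' @param ref_daily reference daily series `data.frame(date, value)` for
#'   the records' pollutant.
#' @param season_windows named list of `c(start, end)` Date pairs.
#' @return the records with `correction`, `adjusted_ugm3`, `clamped` added.
#' @export
adjust_measurements <- function(records, ref_daily, season_windows) {
  records$start_date <- as.Date(records$start_date)
  records$end_date <- as.Date(records$end_date)
  n <- nrow(records)
  correction <- numeric(n)
  for (i in seq_len(n)) {
    win <- season_windows[[records$season[i]]]
    if (is.null(win)) {
      abort_lur("lur_adjust_error", "unknown season '%s'", records$season[i])
    }
    if (records$start_date[i] < win[1] || records$end_date[i] > win[2]) {
      abort_lur(
        "lur_adjust_error",
        "record %s/%s week %s..%s lies outside its season window",
        records$site_id[i], records$pollutant[i],
        records$start_date[i], records$end_date[i]
      )
    }
    days <- ref_daily$date >= records$start_date[i] & ref_daily$date <= records$end_date[i]
    season_days <- ref_daily$date >= win[1] & ref_daily$date <= win[2]
    if (!any(days) || anyNA(ref_daily$value[days])) {
      abort_lur(
        "lur_adjust_error", "reference series does not cover week %s..%s",
        records$start_date[i], records$end_date[i]
      )
    }
    correction[i] <- mean(ref_daily$value[days]) - mean(ref_daily$value[season_days])
  }
  adjusted <- records$value_ugm3 - correction
  records$correction <- correction
  records$clamped <- adjusted < 0
  records$adjusted_ugm3 <- pmax(0, adjusted)
  records
}

#' Seasonal and annual site means from adjusted records
#'
#' Within-season repeats are averaged first; the annual mean is the
#' unweighted mean of the two seasonal means where both exist, else the
#' available one. Sites with no adjusted record in either season are
#' excluded with a warning.
#'
#' @param adjusted output of [adjust_measurements()] (uses
#'   `adjusted_ugm3`).
#' @return data frame `site_id, pollutant, season (warm/cold/annual),
#'   value_ugm3, n_weeks, clamped`.
#' @export
seasonal_means <- function(adjusted) {
  if (nrow(adjusted) == 0L) abort_lur("lur_adjust_error", "no adjusted records")
  out <- list()
  for (poll in unique(adjusted$pollutant)) {
    sub <- adjusted[adjusted$pollutant == poll, ]
    for (sid in unique(sub$site_id)) {
      rows <- sub[sub$site_id == sid, ]
      seas <- list()
      for (season in c("warm", "cold")) {
        rr <- rows[rows$season == season, ]
        if (nrow(rr) > 0L) {
          seas[[season]] <- list(
            value = mean(rr$adjusted_ugm3), n = nrow(rr), clamped = any(rr$clamped)
          )
        }
      }
      if (length(seas) == 0L) {
        warn_lur("lur_adjust_warning", "site %s has no usable %s record in either season", sid, poll)
        next
      }
      for (season in names(seas)) {
        out[[length(out) + 1L]] <- data.frame(
          site_id = sid, pollutant = poll, season = season,
          value_ugm3 = seas[[season]]$value, n_weeks = seas[[season]]$n,
          clamped = seas[[season]]$clamped, stringsAsFactors = FALSE
        )
      }
      out[[length(out) + 1L]] <- data.frame(
        site_id = sid, pollutant = poll, season = "annual",
        value_ugm3 = mean(vapply(seas, `[[`, numeric(1), "value")),
        n_weeks = sum(vapply(seas, `[[`, numeric(1), "n")),
        clamped = any(vapply(seas, `[[`, logical(1), "clamped")),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read adjusted seasonal means as CSV
#'
#' Columns: `site_id, pollutant, season, value_ugm3, n_weeks, clamped`.
#'
#' @param means output of [seasonal_means()].
#' @param path CSV path.
#' @return path (write) or the table (read).
#' @export
write_adjusted_means <- function(means, path) {
  utils::write.csv(means, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjusted_means
#' @export
read_adjusted_means <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
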