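# Synthetic study-world generator. Emulates a two-season passive-sampler
# campaign in a small peri-urban study region: a gridded road network with
# bus/taxi routes, informal point sources (grills, waste burning,
# construction, refuse transfer stations), dwellings, tiled land-use
# polygons, a smooth NDVI-like raster, ~95 monitoring sites stratified by
# proximity to major roads (60/30/10), an hourly reference station with
# gaps, and weekly site measurements scheduled at <= 10 sites at a time.
# Everything is deterministic in the master seed, with one RNG substream
# per layer so that adding a layer never perturbs the others.

#' Configuration of a synthetic monitoring study
#'
#' Defaults state a plausible two-season campaign: a 4 x 3 km region, 95
#' sites split 60/30/10 between near (< 50 m), intermediate (50-100 m) and
#' background (> 100 m) distance to a major road, warm season Nov-Mar and
#' cold season Jun-Sep, at most 10 sites measured in any week, and a
#' reference station whose PM10 seasonal levels follow typical printed
#' values (24.9 / 28.9 ug/m3).
#'
#' @param area_width,area_height study-region dimensions in metres.
#' @param seed master integer seed.
#' @param n_sites number of monitoring sites.
#' @param road_proximity_fractions named proportions (`near`, `intermediate`,
#'   `background`) summing to 1.
#' @param layer_intensities named vector: for point layers, points per km2;
#'   for line layers, km of line per km2 (grid spacing = 2000/intensity m).
#' @param landuse_cell edge of the square land-use tiles, metres.
#' @param landuse_probs named probabilities of each land-use category.
#' @param season_windows named list of `c(start, end)` ISO date pairs for
#'   `warm` and `cold`; must be disjoint.
#' @param weekly_capacity maximum sites measured simultaneously.
#' @param true_model list with `intercept` (ug/m3) and `terms`, a list of
#'   `list(spec = predictor_spec, coef = …)`; see [default_true_model()].
#' @param season_offsets additive ug/m3 shift of true site means per season.
#' @param noise_sd iid measurement noise sd, ug/m3 (passive-sampler error;
#'   free parameter, not calibrated to any campaign).
#' @param ref_gap_fraction fraction of reference hours deleted at random.
#' @param no2_cutover ISO date after which reference NO2 is missing
#'   entirely (mimicking a monitor decommissioned mid-study); `NA` disables.
#' @param lost_fraction fraction of weekly measurements lost.
#' @param ref_params reference-station generative settings (seasonal PM10
#'   means, AR(1) day-to-day autocorrelation, noise sds, solar peak W/m2,
#'   NO2 linear coefficients on PM10 and solar).
#' @return a `study_config` list, validated.
#' @export
study_config <- function(area_width = 4000, area_height = 3000, seed = 1,
                         n_sites = 95,
                         road_proximity_fractions = c(near = 0.6, intermediate = 0.3, background = 0.1),
                         layer_intensities = c(
                           major_road = 4, minor_road = 16, rail = 0.6,
                           bus_stop = 8, grill = 3, burn_site = 2,
                           construction = 1.5, refuse_station = 0.6,
                           dwelling = 350, train_station = 0.4
                         ),
                         landuse_cell = 250,
                         landuse_probs = c(
                           residential = 0.45, commercial = 0.1, industrial = 0.1,
                           open_space = 0.15, vegetation = 0.2
                         ),
                         season_windows = list(
                           warm = c("2015-11-02", "2016-03-27"),
                           cold = c("2016-06-06", "2016-09-25")
                         ),
                         weekly_capacity = 10,
                         true_model = default_true_model(),
                         season_offsets = c(warm = -4, cold = 4),
                         noise_sd = 2,
                         ref_gap_fraction = 0.02,
                         no2_cutover = "2016-01-15",
                         lost_fraction = 0.04,
                         ref_params = list(
                           pm10_season_mean = c(warm = 24.9, cold = 28.9),
                           ar1_phi = 0.7, daily_sd = 6, hourly_sd = 3,
                           solar_peak = 900,
                           no2_coef = c(intercept = 17.35, pm10 = 1, solar = -0.07),
                           no2_noise_sd = 2
                         )) {
  if (!is_scalar_number(area_width) || !is_scalar_number(area_height) ||
    area_width <= 0 || area_height <= 0) {
    abort_lur("lur_config_error", "study area must have positive width and height")
  }
  if (abs(sum(road_proximity_fractions) - 1) > 1e-9 || any(road_proximity_fractions < 0)) {
    abort_lur("lur_config_error", "road_proximity_fractions must be non-negative and sum to 1")
  }
  if (any(layer_intensities < 0)) abort_lur("lur_config_error", "layer intensities must be >= 0")
  if (noise_sd < 0) abort_lur("lur_config_error", "noise_sd must be >= 0")
  if (ref_gap_fraction < 0 || ref_gap_fraction >= 1) {
    abort_lur("lur_config_error", "ref_gap_fraction must be in [0, 1)")
  }
  sw <- lapply(season_windows, as.Date)
  if (!setequal(names(sw), c("warm", "cold"))) {
    abort_lur("lur_config_error", "season_windows must be named 'warm' and 'cold'")
  }
  if (sw$warm[2] >= sw$cold[1] && sw$cold[2] >= sw$warm[1]) {
    overlap <- max(sw$warm[1], sw$cold[1]) <= min(sw$warm[2], sw$cold[2])
    if (overlap) abort_lur("lur_config_error", "season windows must be disjoint")
  }
  structure(
    list(
      area_width = area_width, area_height = area_height, seed = as.integer(seed),
      n_sites = as.integer(n_sites),
      road_proximity_fractions = road_proximity_fractions,
      layer_intensities = layer_intensities,
      landuse_cell = landuse_cell, landuse_probs = landuse_probs,
      season_windows = sw, weekly_capacity = as.integer(weekly_capacity),
      true_model = true_model, season_offsets = season_offsets,
      noise_sd = noise_sd, ref_gap_fraction = ref_gap_fraction,
      no2_cutover = if (is.na(no2_cutover)) as.Date(NA) else as.Date(no2_cutover),
      lost_fraction = lost_fraction, ref_params = ref_params
    ),
    class = "study_config"
  )
}

#' Default generative exposure model
#'
#' Three active predictors chosen from the classical LUR repertoire: major
#' road length in 300 m (+), grill count in 1000 m (+), and mean NDVI in
#' 500 m (-), around an 18 ug/m3 intercept. Coefficients are scaled so each
#' term moves site means by a few ug/m3 across the region.
#'
#' @return list with `intercept` and `terms` (spec + coefficient pairs).
#' @export
default_true_model <- function() {
  list(
    intercept = 18,
    terms = list(
      list(spec = predictor_spec("MAJROAD_300", "major_road", "length", 300, "+"), coef = 0.004),
      list(spec = predictor_spec("GRILL_1000", "grill", "count", 1000, "+"), coef = 0.5),
      list(spec = predictor_spec("NDVI_500", "raster", "raster_mean", 500, "-"), coef = -8)
    )
  )
}

grid_lines <- function(spacing, width, height, jitter_x, jitter_y) {
  xs <- seq(jitter_x %% spacing, width, by = spacing)
  ys <- seq(jitter_y %% spacing, height, by = spacing)
  c(
    lapply(xs, function(x) rbind(c(x, 0), c(x, height))),
    lapply(ys, function(y) rbind(c(0, y), c(width, y)))
  )
}

poisson_points <- function(intensity, width, height) {
  n <- stats::rpois(1, intensity * width * height / 1e6)
  cbind(stats::runif(n, 0, width), stats::runif(n, 0, height))
}

#' Generate the synthetic GIS layers and NDVI-like raster
#'
#' Produces one layer per configured category: a grid-aligned major-road
#' network plus minor roads (combined into an all-roads layer), bus and taxi
#' routes as subsets of the road polylines, a rail line with train stations
#' on it, informal point sources and dwellings from homogeneous Poisson
#' processes, land-use polygons tiling the region without overlap, a coast
#' line along the western edge, and a smooth raster field scaled to [-1, 1]
#' standing in for NDVI. The raster extends 760 m beyond the study region so
#' that every canonical raster buffer fits.
#'
#' @param config a [study_config()].
#' @return list with `layers` (named list of [feature_layer()]) and
#'   `raster` (an [ascii_grid()]).
#' @export
generate_layers <- function(config) {
  stopifnot(inherits(config, "study_config"))
  W <- config$area_width
  H <- config$area_height
  li <- config$layer_intensities
  layers <- list()

  road_spacing <- function(intensity) 2000 / intensity
  major <- with_substream(config$seed, "major_road", {
    grid_lines(
      road_spacing(li[["major_road"]]), W, H,
      stats::runif(1, 0, W), stats::runif(1, 0, H)
    )
  })
  layers$major_road <- feature_layer("major_road", "lines", major, "+")

  minor <- with_substream(config$seed, "minor_road", {
    grid_lines(
      road_spacing(li[["minor_road"]]), W, H,
      stats::runif(1, 0, W), stats::runif(1, 0, H)
    )
  })
  layers$road <- feature_layer("road", "lines", c(major, minor), "+")

  nroad <- length(layers$road$geoms)
  layers$bus_route <- with_substream(config$seed, "bus_route", {
    keep <- sort(sample.int(nroad, max(1L, round(0.3 * nroad))))
    feature_layer("bus_route", "lines", layers$road$geoms[keep], "+")
  })
  layers$taxi_route <- with_substream(config$seed, "taxi_route", {
    keep <- sort(sample.int(nroad, max(1L, round(0.4 * nroad))))
    feature_layer("taxi_route", "lines", layers$road$geoms[keep], "+")
  })

  layers$rail <- with_substream(config$seed, "rail", {
    n <- max(1L, round(li[["rail"]] * H / 1000))
    ys <- stats::runif(n, 0.1 * H, 0.9 * H)
    feature_layer("rail", "lines", lapply(ys, function(y) rbind(c(0, y), c(W, y))), "+")
  })
  layers$train_station <- with_substream(config$seed, "train_station", {
    n <- max(1L, stats::rpois(1, li[["train_station"]] * W * H / 1e6))
    seg <- layers$rail$geoms[[1]]
    xs <- stats::runif(n, 0, W)
    feature_layer("train_station", "points", cbind(xs, rep(seg[1, 2], n)), "+")
  })

  for (cat in c("bus_stop", "grill", "burn_site", "construction", "refuse_station", "dwelling")) {
    layers[[cat]] <- with_substream(config$seed, cat, {
      pts <- poisson_points(li[[cat]], W, H)
      if (nrow(pts) == 0L) pts <- cbind(stats::runif(1, 0, W), stats::runif(1, 0, H))
      feature_layer(cat, "points", pts, "+")
    })
  }

  layers$airport <- with_substream(config$seed, "airport", {
    feature_layer("airport", "points", cbind(stats::runif(1, 0, W), stats::runif(1, 0, H)), "+")
  })
  layers$coast <- feature_layer(
    "coast", "lines", list(rbind(c(0, 0), c(0, H))), "-"
  )

  # Land-use tiling: square cells assigned categorically; each category's
  # layer holds its own cells, so within-layer overlap is structurally zero.
  lu_cats <- names(config$landuse_probs)
  lu_signs <- c(
    residential = "+", commercial = "+", industrial = "+",
    open_space = "-", vegetation = "-", water = "-",
    public = "+", transport = "+", restaurant = "+"
  )
  cell <- config$landuse_cell
  nx <- ceiling(W / cell)
  ny <- ceiling(H / cell)
  assignment <- with_substream(config$seed, "landuse", {
    sample(lu_cats, nx * ny, replace = TRUE, prob = config$landuse_probs)
  })
  idx <- 0L
  tiles <- stats::setNames(vector("list", length(lu_cats)), lu_cats)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      idx <- idx + 1L
      x0 <- (j - 1) * cell
      y0 <- (i - 1) * cell
      x1 <- min(j * cell, W)
      y1 <- min(i * cell, H)
      cat <- assignment[idx]
      tiles[[cat]] <- c(tiles[[cat]], list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))))
    }
  }
  for (cat in lu_cats) {
    if (length(tiles[[cat]]) > 0L) {
      layers[[paste0("landuse_", cat)]] <- feature_layer(
        paste0("landuse_", cat), "polygons", tiles[[cat]],
        lu_signs[[cat]] %||% "+"
      )
    }
  }

  raster <- with_substream(config$seed, "ndvi", {
    margin <- 760
    cellsize <- 30
    nxr <- ceiling((W + 2 * margin) / cellsize)
    nyr <- ceiling((H + 2 * margin) / cellsize)
    xs <- -margin + (seq_len(nxr) - 0.5) * cellsize
    ys <- -margin + (nyr - seq_len(nyr) + 0.5) * cellsize
    f <- matrix(0, nyr, nxr)
    for (k in 1:5) {
      wx <- stats::runif(1, 0.5, 3) * 2 * pi / W
      wy <- stats::runif(1, 0.5, 3) * 2 * pi / H
      ph <- stats::runif(2, 0, 2 * pi)
      amp <- stats::rnorm(1, 0, 1 / k)
      f <- f + amp * outer(ys, xs, function(y, x) cos(wx * x + ph[1]) * cos(wy * y + ph[2]))
    }
    ascii_grid(tanh(f / stats::sd(f)), xll = -margin, yll = -margin, cellsize = cellsize)
  })

  list(layers = layers, raster = raster)
}

classify_road_proximity <- function(d) {
  ifelse(d < 50, "near", ifelse(d <= 100, "intermediate", "background"))
}

# Largest-remainder apportionment of n into the target fractions.
quota_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Sample stratified monitoring sites
#'
#' Draws uniform points in the study region and keeps them by
#' distance-to-nearest-major-road class until each class quota (largest
#' remainder apportionment of the configured fractions) is filled. Classes:
#' near < 50 m, intermediate 50-100 m (inclusive), background > 100 m.
#'
#' @param config a [study_config()].
#' @param layers layer list from [generate_layers()] (needs `major_road`).
#' @return data frame `site_id, x, y, class, dist_major_road, area` (area is
#'   a west/centre/east block label, cosmetic only).
#' @export
sample_sites <- function(config, layers) {
  major <- layers$major_road
  if (is.null(major)) abort_lur("lur_generation_error", "major_road layer is required")
  quotas <- quota_counts(config$n_sites, config$road_proximity_fractions)
  segs <- segment_table(major$geoms)
  with_substream(config$seed, "sites", {
    got <- stats::setNames(numeric(3), names(quotas))
    xs <- ys <- ds <- numeric(0)
    cls <- character(0)
    max_draws <- 4000 * config$n_sites
    draws <- 0L
    while (any(got < quotas) && draws < max_draws) {
      m <- 256L
      draws <- draws + m
      px <- stats::runif(m, 0, config$area_width)
      py <- stats::runif(m, 0, config$area_height)
      for (i in seq_len(m)) {
        d <- min(point_segment_distance(px[i], py[i], segs[, "ax"], segs[, "ay"], segs[, "bx"], segs[, "by"]))
        k <- classify_road_proximity(d)
        if (got[[k]] < quotas[[k]]) {
          got[[k]] <- got[[k]] + 1
          xs <- c(xs, px[i])
          ys <- c(ys, py[i])
          ds <- c(ds, d)
          cls <- c(cls, k)
        }
      }
    }
    short <- names(quotas)[got < quotas]
    if (length(short) > 0L) {
      abort_lur(
        "lur_generation_error",
        "could not place enough '%s' sites (need %s, got %s): area too small relative to the major-road spacing",
        short[1], quotas[[short[1]]], got[[short[1]]]
      )
    }
    data.frame(
      site_id = sprintf("S%03d", seq_along(xs)),
      x = xs, y = ys, class = cls, dist_major_road = ds,
      area = c("west", "centre", "east")[pmin(3, 1 + floor(3 * xs / config$area_width))],
      stringsAsFactors = FALSE
    )
  })
}

#' Generate the hourly reference-station series
#'
#' PM10 follows a seasonal base level with AR(1) day-to-day deviations and
#' hourly noise (clamped at 0); solar radiation has a clear diurnal cycle
#' (zero outside 06:00-18:00) with a per-day cloud factor; NO2 is a
#' configured linear function of PM10 and solar plus noise; temperature is
#' cosmetic. A `ref_gap_fraction` of hours is blanked at random across all
#' channels, and NO2 is blanked entirely after the cut-over date. The
#' complete (pre-gap) series is kept in `attr(, "complete")`.
#'
#' @param config a [study_config()].
#' @return data frame `timestamp (POSIXct UTC), pm10, no2, solar, temp`.
#' @export
generate_reference_series <- function(config) {
  stopifnot(inherits(config, "study_config"))
  p <- config$ref_params
  start <- config$season_windows$warm[1]
  end <- config$season_windows$cold[2]
  days <- seq(start, end, by = "day")
  nd <- length(days)
  base <- seasonal_base_level(days, config$season_windows, p$pm10_season_mean)
  with_substream(config$seed, "reference", {
    dev <- numeric(nd)
    dev[1] <- stats::rnorm(1, 0, p$daily_sd)
    for (d in 2:nd) {
      dev[d] <- p$ar1_phi * dev[d - 1] + stats::rnorm(1, 0, p$daily_sd * sqrt(1 - p$ar1_phi^2))
    }
    cloud <- stats::runif(nd, 0.5, 1)
    hours <- 0:23
    ts <- as.POSIXct(rep(days, each = 24), tz = "UTC") + rep(hours, nd) * 3600
    hod <- rep(hours, nd)
    day_idx <- rep(seq_len(nd), each = 24)
    pm10 <- pmax(0, base[day_idx] + dev[day_idx] +
      3 * sin(2 * pi * (hod - 8) / 24) + stats::rnorm(nd * 24, 0, p$hourly_sd))
    solar <- p$solar_peak * cloud[day_idx] * pmax(0, sin(pi * (hod - 6) / 12))
    solar[hod < 6 | hod > 18] <- 0
    no2 <- p$no2_coef[["intercept"]] + p$no2_coef[["pm10"]] * pm10 +
      p$no2_coef[["solar"]] * solar + stats::rnorm(nd * 24, 0, p$no2_noise_sd)
    temp <- 18 + 6 * sin(pi * (hod - 6) / 12) - 4 * (base[day_idx] > mean(base)) +
      stats::rnorm(nd * 24, 0, 1)
    complete <- data.frame(timestamp = ts, pm10 = pm10, no2 = no2, solar = solar, temp = temp)
    out <- complete
    if (config$ref_gap_fraction > 0) {
      gap <- sample.int(nrow(out), round(config$ref_gap_fraction * nrow(out)))
      out[gap, c("pm10", "no2", "solar", "temp")] <- NA_real_
    }
    if (!is.na(config$no2_cutover)) {
      out$no2[as.Date(out$timestamp, tz = "UTC") >= config$no2_cutover] <- NA_real_
    }
    attr(out, "complete") <- complete
    out
  })
}

# Seasonal base level with a linear ramp across the between-season gap.
seasonal_base_level <- function(days, windows, season_means) {
  warm <- windows$warm
  cold <- windows$cold
  out <- numeric(length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    out[i] <- if (d >= warm[1] && d <= warm[2]) {
      season_means[["warm"]]
    } else if (d >= cold[1] && d <= cold[2]) {
      season_means[["cold"]]
    } else if (d > warm[2] && d < cold[1]) {
      f <- as.numeric(d - warm[2]) / as.numeric(cold[1] - warm[2])
      (1 - f) * season_means[["warm"]] + f * season_means[["cold"]]
    } else {
      season_means[[if (d < warm[1]) "warm" else "cold"]]
    }
  }
  out
}

#' Build the measurement schedule
#'
#' Sites are measured once per season for one calendar week, at most
#' `weekly_capacity` sites in any week. Site order is permuted per season
#' (seeded); consecutive blocks of `weekly_capacity` sites share a week.
#'
#' @param sites site table from [sample_sites()].
#' @param config a [study_config()].
#' @return data frame `site_id, season, week_start, week_end`.
#' @export
make_schedule <- function(sites, config) {
  out <- list()
  for (season in c("warm", "cold")) {
    win <- config$season_windows[[season]]
    week_starts <- seq(win[1], win[2] - 6, by = "7 days")
    needed <- ceiling(nrow(sites) / config$weekly_capacity)
    if (needed > length(week_starts)) {
      abort_lur(
        "lur_schedule_error",
        "schedule infeasible: %d sites at capacity %d need %d weeks but the %s season has %d",
        nrow(sites), config$weekly_capacity, needed, season, length(week_starts)
      )
    }
    ord <- with_substream(config$seed, paste0("schedule_", season), sample.int(nrow(sites)))
    wk <- week_starts[((seq_along(ord) - 1) %/% config$weekly_capacity) + 1]
    out[[season]] <- data.frame(
      site_id = sites$site_id[ord], season = season,
      week_start = wk, week_end = wk + 6, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

ref_week_deviation <- function(ref_daily, week_start, week_end, window) {
  in_week <- ref_daily$date >= week_start & ref_daily$date <= week_end
  in_season <- ref_daily$date >= window[1] & ref_daily$date <= window[2]
  mean(ref_daily$value[in_week]) - mean(ref_daily$value[in_season])
}

#' Assemble the ground truth of the synthetic study
#'
#' Computes true seasonal site means from the configured generative model
#' (intercept + sum of coefficient times extracted predictor + seasonal
#' offset, clamped at 0) and the weekly regional deviations of the
#' reference station from its seasonal mean, for both pollutants, at the
#' daily resolution the temporal-adjustment stage works at.
#'
#' @param sites,layers,raster study components.
#' @param ref_daily named list of daily reference series (`pm25`, `no2`),
#'   each `data.frame(date, value)` — normally from the complete hourly
#'   record via [daily_from_hourly()] and [estimate_pm25()].
#' @param schedule from [make_schedule()].
#' @param config a [study_config()].
#' @return a `synthetic_truth` list: `true_coefficients`, `true_site_means`
#'   (site x season data frame, per pollutant identical spatial surface),
#'   `ref_deviations`, and the active-term predictor matrix.
#' @export
synthetic_truth <- function(sites, layers, raster, ref_daily, schedule, config) {
  tm <- config$true_model
  specs <- lapply(tm$terms, `[[`, "spec")
  coefs <- vapply(tm$terms, `[[`, numeric(1), "coef")
  names(coefs) <- vapply(specs, `[[`, character(1), "name")
  for (i in seq_along(specs)) {
    if (sign(coefs[i]) != ifelse(specs[[i]]$expected_sign == "+", 1, -1)) {
      abort_lur(
        "lur_config_error", "true coefficient of %s contradicts its expected sign",
        specs[[i]]$name
      )
    }
  }
  X <- build_predictor_matrix(specs, layers, sites, raster)
  surface <- tm$intercept + as.numeric(X$values %*% coefs)
  means <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  clamped <- FALSE
  for (season in c("warm", "cold")) {
    v <- surface + config$season_offsets[[season]]
    clamped <- clamped || any(v < 0)
    means[[season]] <- pmax(0, v)
  }
  means$annual <- (means$warm + means$cold) / 2

  weeks <- unique(schedule[, c("season", "week_start", "week_end")])
  devs <- do.call(rbind, lapply(names(ref_daily), function(poll) {
    data.frame(
      pollutant = poll, season = weeks$season, week_start = weeks$week_start,
      deviation = mapply(function(s, ws, we) {
        ref_week_deviation(ref_daily[[poll]], ws, we, config$season_windows[[s]])
      }, weeks$season, weeks$week_start, weeks$week_end),
      stringsAsFactors = FALSE
    )
  }))
  rownames(devs) <- NULL
  structure(
    list(
      true_coefficients = c(intercept = tm$intercept, coefs),
      true_site_means = means, ref_deviations = devs,
      active_matrix = X, any_clamped = clamped
    ),
    class = "synthetic_truth"
  )
}

#' Generate weekly site measurements
#'
#' Each scheduled record's value is the site's true seasonal mean plus the
#' reference station's deviation for that week plus iid noise; a configured
#' fraction of records is then lost uniformly at random. The additive
#' decomposition of every surviving record (true mean, deviation, noise
#' draw) is kept in `attr(, "components")` so values can be regenerated
#' exactly from the stored pieces.
#'
#' @param sites site table.
#' @param truth a [synthetic_truth()].
#' @param schedule from [make_schedule()].
#' @param config a [study_config()].
#' @return data frame `site_id, pollutant, season, start_date, end_date,
#'   value_ugm3`.
#' @export
generate_measurements <- function(sites, truth, schedule, config) {
  pollutants <- unique(truth$ref_deviations$pollutant)
  recs <- do.call(rbind, lapply(pollutants, function(poll) {
    df <- schedule
    df$pollutant <- poll
    df
  }))
  key <- match(
    paste(recs$pollutant, recs$season, recs$week_start),
    paste(
      truth$ref_deviations$pollutant, truth$ref_deviations$season,
      truth$ref_deviations$week_start
    )
  )
  dev <- truth$ref_deviations$deviation[key]
  tm <- truth$true_site_means
  true_mean <- mapply(
    function(sid, season) tm[[season]][tm$site_id == sid],
    recs$site_id, recs$season
  )
  noise <- with_substream(
    config$seed, "measurement_noise",
    stats::rnorm(nrow(recs), 0, config$noise_sd)
  )
  out <- data.frame(
    site_id = recs$site_id, pollutant = recs$pollutant, season = recs$season,
    start_date = recs$week_start, end_date = recs$week_end,
    value_ugm3 = true_mean + dev + noise, stringsAsFactors = FALSE
  )
  comp <- data.frame(
    site_id = recs$site_id, pollutant = recs$pollutant, season = recs$season,
    start_date = recs$week_start,
    true_mean = true_mean, deviation = dev, noise = noise
  )
  if (config$lost_fraction > 0) {
    lost <- with_substream(
      config$seed, "lost_samples",
      sample.int(nrow(out), round(config$lost_fraction * nrow(out)))
    )
    if (length(lost) > 0L) {
      out <- out[-lost, ]
      comp <- comp[-lost, ]
    }
  }
  rownames(out) <- rownames(comp) <- NULL
  attr(out, "components") <- comp
  out
}

#' Generate a complete synthetic study
#'
#' One-shot wrapper running [generate_layers()], [sample_sites()],
#' [generate_reference_series()], the daily reduction of the complete
#' reference record, [make_schedule()], [synthetic_truth()] and
#' [generate_measurements()].
#'
#' @param config a [study_config()].
#' @return list `config, layers, raster, sites, ref_hourly, ref_daily,
#'   schedule, truth, measurements`.
#' @export
synthetic_study <- function(config = study_config()) {
  gen <- generate_layers(config)
  sites <- sample_sites(config, gen$layers)
  ref_hourly <- generate_reference_series(config)
  complete <- attr(ref_hourly, "complete")
  pm10_daily <- daily_from_hourly(complete$timestamp, complete$pm10)
  ref_daily <- list(
    pm25 = estimate_pm25(pm10_daily),
    no2 = daily_from_hourly(complete$timestamp, complete$no2)
  )
  schedule <- make_schedule(sites, config)
  truth <- synthetic_truth(sites, gen$layers, gen$raster, ref_daily, schedule, config)
  measurements <- generate_measurements(sites, truth, schedule, config)
  list(
    config = config, layers = gen$layers, raster = gen$raster, sites = sites,
    ref_hourly = ref_hourly, ref_daily = ref_daily, schedule = schedule,
    truth = truth, measurements = measurements
  )
}

#' Write the synthetic study to plain-text files
#'
#' Vector layers as GeoJSON, the raster as ESRI ASCII, sites and
#' measurements and the reference series as CSV with ISO-8601 dates.
#'
#' @param study output of [synthetic_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layers_geojson(study$layers, file.path(dir, "layers"))
  write_ascii_grid(study$raster, file.path(dir, "ndvi.asc"))
  utils::write.csv(
    study$sites[, c("site_id", "x", "y", "class")],
    file.path(dir, "sites.csv"),
    row.names = FALSE
  )
  meas <- study$measurements
  meas$start_date <- format(meas$start_date)
  meas$end_date <- format(meas$end_date)
  utils::write.csv(meas, file.path(dir, "measurements.csv"), row.names = FALSE)
  ref <- study$ref_hourly
  ref$timestamp <- format(ref$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(ref, file.path(dir, "reference_hourly.csv"), row.names = FALSE, na = "")
  tm <- study$truth$true_site_means
  utils::write.csv(tm, file.path(dir, "truth_site_means.csv"), row.names = FALSE)
  invisible(dir)
}
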