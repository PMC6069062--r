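test_that("buffer counts use the closed disc and reject mismatched geometry", {
  pts <- feature_layer("grill", "points", rbind(c(200, 0), c(50, 0), c(100, 0)))
  sites <- unit_sites(rbind(c(0, 0)))
  expect_equal(buffer_aggregate(pts, sites, 100, "count"), 2)
  # a point exactly on the boundary counts as inside
  expect_equal(buffer_aggregate(pts, sites, 200, "count"), 3)
  expect_equal(buffer_aggregate(pts, sites, 10, "count"), 0)
  expect_error(buffer_aggregate(pts, sites, 100, "length"), class = "lur_type_error")
  expect_error(buffer_aggregate(pts, sites, -5, "count"), class = "lur_geometry_error")
})

test_that("clipped polygon area reproduces the full-disc analytic value", {
  cover <- feature_layer("landuse_residential", "polygons",
    list(rbind(c(-500, -500), c(500, -500), c(500, 500), c(-500, 500))), "+")
  sites <- unit_sites(rbind(c(0, 0)))
  expect_equal(buffer_aggregate(cover, sites, 100, "area"), pi * 1e4, tolerance = 1e-9)
})

test_that("clipped length agrees with the dense-resampling oracle on seeded cases", {
  set.seed(77)
  sites <- unit_sites(rbind(c(0, 0)))
  for (k in 1:10) {
    layer <- feature_layer("road", "lines", list(random_polyline(6)), "+")
    r <- stats::runif(1, 30, 120)
    got <- buffer_aggregate(layer, sites, r, "length")
    want <- oracle_clipped_length(layer$geoms, 0, 0, r, step = 0.05)
    expect_lt(abs(got - want), max(0.005 * want, 0.2))
  }
})

test_that("nearest distance is exact and distinguishes empty layers from zero distance", {
  seg <- feature_layer("major_road", "lines", list(rbind(c(3, 0), c(3, 10))))
  expect_equal(nearest_distance(seg, unit_sites(rbind(c(0, 0)))), 3.0)
  expect_equal(nearest_distance(seg, unit_sites(rbind(c(3, 5)))), 0)
  empty <- feature_layer("rail", "points", matrix(numeric(0), 0, 2))
  expect_error(nearest_distance(empty, unit_sites(rbind(c(0, 0)))), class = "lur_empty_layer_error")

  set.seed(88)
  layer <- l_line_layer()
  for (k in 1:20) {
    p <- stats::runif(2, -100, 250)
    expect_equal(
      nearest_distance(layer, unit_sites(rbind(p))),
      oracle_min_distance(p[1], p[2], layer$geoms),
      tolerance = 1e-9
    )
  }
})

test_that("distance transforms floor at the configured minimum and are monotone", {
  tr <- distance_transforms(50, floor = 1)
  expect_equal(tr$inv, 0.02)
  expect_equal(tr$inv_sq, 4e-4)
  tr0 <- distance_transforms(0, floor = 1)
  expect_equal(tr0$inv, 1.0)
  expect_equal(tr0$inv_sq, 1.0)
  d <- seq(1, 500, by = 7)
  tr2 <- distance_transforms(d)
  expect_true(all(diff(tr2$inv) <= 0))
  expect_true(all(diff(tr2$inv_sq) <= 0))
  expect_error(distance_transforms(10, floor = 0), class = "lur_geometry_error")
})

test_that("raster buffer means match the exhaustive cell-scan oracle and stay within bounds", {
  const <- ascii_grid(matrix(0.4, 20, 20), 0, 0, 30)
  sites <- unit_sites(rbind(c(300, 300)))
  expect_equal(raster_buffer_mean(const, sites, 100), 0.4)

  set.seed(99)
  ras <- ascii_grid(matrix(stats::runif(400, -1, 1), 20, 20), 0, 0, 30)
  for (r in c(60, 100, 150)) {
    got <- raster_buffer_mean(ras, sites, r)
    expect_equal(got, oracle_raster_mean(ras, 300, 300, r), tolerance = 1e-12)
    expect_gte(got, min(ras$values))
    expect_lte(got, max(ras$values))
  }

  err <- expect_error(
    raster_buffer_mean(ras, data.frame(site_id = "edge_site", x = 20, y = 300), 100),
    class = "lur_raster_extent_error"
  )
  expect_match(conditionMessage(err), "edge_site")
})

test_that("matrix assembly dispatches, carries metadata, and reports structural errors", {
  layer_pts <- feature_layer("grill", "points", rbind(c(10, 10), c(400, 400)))
  layer_lin <- l_line_layer()
  ras <- ascii_grid(matrix(0.2, 80, 80), -600, -600, 30)
  sites <- unit_sites(rbind(c(100, 80), c(300, 200)))
  specs <- list(
    predictor_spec("GRILL_300", "grill", "count", 300, "+"),
    predictor_spec("MAJROAD_100", "major_road", "length", 100, "+"),
    predictor_spec("MAJROAD_d_inv", "major_road", "inverse_distance", expected_sign = "+"),
    predictor_spec("NDVI_100", "raster", "raster_mean", 100, "-")
  )
  pm <- build_predictor_matrix(specs, list(grill = layer_pts, major_road = layer_lin), sites, ras)
  expect_equal(dim(pm$values), c(2L, 4L))
  expect_identical(colnames(pm$values), vapply(specs, `[[`, character(1), "name"))
  expect_identical(pm$specs$NDVI_100$expected_sign, "-")
  expect_true(all(pm$values[, "GRILL_300"] == floor(pm$values[, "GRILL_300"])))
  expect_true(all(pm$values[, "MAJROAD_d_inv"] > 0))
  expect_false(anyNA(pm$values))

  dup <- c(specs, list(predictor_spec("GRILL_300", "grill", "count", 500, "+")))
  expect_error(
    build_predictor_matrix(dup, list(grill = layer_pts, major_road = layer_lin), sites, ras),
    class = "lur_spec_error"
  )
  err <- expect_error(
    build_predictor_matrix(specs, list(grill = layer_pts), sites, ras),
    class = "lur_missing_layer_error"
  )
  expect_match(conditionMessage(err), "major_road")
})

test_that("buffered aggregations are monotone in radius and translation invariant", {
  st <- synthetic_study(tiny_config(n_sites = 8))
  layers <- st$layers
  sites <- st$sites
  for (case in list(
    list(layer = layers$grill, agg = "count"),
    list(layer = layers$road, agg = "length"),
    list(layer = layers$landuse_residential, agg = "area")
  )) {
    prev <- NULL
    for (r in c(50, 100, 300, 1000)) {
      cur <- buffer_aggregate(case$layer, sites, r, case$agg)
      if (!is.null(prev)) expect_true(all(cur >= prev - 1e-9))
      prev <- cur
    }
    # clipped area can never exceed the disc, length never the layer total
    if (case$agg == "area") expect_true(all(cur <= pi * 1000^2 + 1e-6))
    if (case$agg == "length") {
      total <- sum(vapply(case$layer$geoms, function(m) {
        sum(sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
      }, numeric(1)))
      expect_true(all(cur <= total + 1e-9))
    }
  }

  shift <- c(12345.6, -9876.5)
  shifted_layers <- lapply(layers[c("grill", "road", "landuse_residential")], function(L) {
    g <- if (L$type == "points") sweep(L$geoms, 2, -shift) else lapply(L$geoms, function(m) sweep(m, 2, -shift))
    feature_layer(L$category, L$type, g, L$expected_sign)
  })
  s2 <- sites
  s2$x <- s2$x + shift[1]
  s2$y <- s2$y + shift[2]
  for (nm in names(shifted_layers)) {
    agg <- switch(shifted_layers[[nm]]$type, points = "count", lines = "length", polygons = "area")
    expect_equal(
      buffer_aggregate(shifted_layers[[nm]], s2, 300, agg),
      buffer_aggregate(layers[[nm]], sites, 300, agg),
      tolerance = 1e-9
    )
  }
})

test_that("predictor matrices round-trip through CSV + JSON sidecar", {
  st <- synthetic_study(tiny_config(n_sites = 6))
  specs <- list(
    predictor_spec("GRILL_500", "grill", "count", 500, "+"),
    predictor_spec("NDVI_200", "raster", "raster_mean", 200, "-")
  )
  pm <- build_predictor_matrix(specs, st$layers, st$sites, st$raster)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pm.csv")
  write_predictor_matrix(pm, path)
  back <- read_predictor_matrix(path)
  expect_equal(back$values, pm$values, tolerance = 1e-12)
  expect_identical(
    lapply(back$specs, unclass),
    lapply(pm$specs, unclass)
  )
})

test_that("canonical radius sets are enforced unless explicitly relaxed", {
  expect_error(predictor_spec("X_77", "grill", "count", 77, "+"), class = "lur_spec_error")
  expect_error(predictor_spec("NDVI_25", "raster", "raster_mean", 25, "-"), class = "lur_spec_error")
  expect_silent(predictor_spec("X_77", "grill", "count", 77, "+", allow_any_radius = TRUE))
  expect_error(predictor_spec("bad name", "grill", "count", 100, "+"), class = "lur_spec_error")
})
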