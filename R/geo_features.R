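# Buffer-based GIS predictor engineering. Every predictor is an exact
# geometric aggregate around a monitoring site: point counts, clipped
# polyline length or polygon area inside a disc, raster means over cell
# centres in a disc, or a nearest-feature distance with inverse and
# inverse-squared transforms. Boundary convention: a feature exactly on the
# disc boundary is inside (closed disc).

VECTOR_RADII <- c(25, 50, 100, 300, 500, 1000)
RASTER_RADII <- c(30, 100, 150, 200, 500, 750)
AGGREGATIONS <- c(
  "count", "length", "area", "raster_mean",
  "distance", "inverse_distance", "inverse_sq_distance"
)

#' Define a predictor
#'
#' A predictor spec names one engineered variable: which layer it comes
#' from, how it is aggregated, at which buffer radius (for buffered
#' aggregations), and the a-priori expected direction of its effect on
#' concentration, used later as a veto during supervised forward selection.
#'
#' @param name column name, e.g. `"MAJROAD_300"` or `"BUS_ST_d_inv"`.
#' @param source_category category tag of the source layer (or `"ndvi"`-style
#'   raster tag for `raster_mean`).
#' @param aggregation one of count, length, area, raster_mean, distance,
#'   inverse_distance, inverse_sq_distance.
#' @param buffer_radius metres; required for buffered aggregations and drawn
#'   from the canonical radius sets (25/50/100/300/500/1000 m for vector
#'   layers, 30/100/150/200/500/750 m for raster means) unless
#'   `allow_any_radius = TRUE`.
#' @param expected_sign `"+"` or `"-"`.
#' @param allow_any_radius set `TRUE` to permit non-canonical radii.
#' @return a `predictor_spec`.
#' @export
predictor_spec <- function(name, source_category, aggregation, buffer_radius = NULL,
                           expected_sign = "+", allow_any_radius = FALSE) {
  if (!aggregation %in% AGGREGATIONS) {
    abort_lur("lur_spec_error", "unknown aggregation '%s'", aggregation)
  }
  if (!expected_sign %in% c("+", "-")) {
    abort_lur("lur_spec_error", "expected_sign must be '+' or '-' (%s)", name)
  }
  if (name != make.names(name)) {
    abort_lur("lur_spec_error", "predictor name '%s' must be a syntactic R name", name)
  }
  buffered <- aggregation %in% c("count", "length", "area", "raster_mean")
  if (buffered) {
    if (is.null(buffer_radius) || !is_scalar_number(buffer_radius) || buffer_radius <= 0) {
      abort_lur("lur_spec_error", "%s: buffered aggregation needs a positive buffer_radius", name)
    }
    buffer_radius <- as.numeric(buffer_radius)
    canon <- if (aggregation == "raster_mean") RASTER_RADII else VECTOR_RADII
    if (!allow_any_radius && !buffer_radius %in% canon) {
      abort_lur(
        "lur_spec_error", "%s: radius %g not in canonical set {%s}",
        name, buffer_radius, paste(canon, collapse = ",")
      )
    }
  } else {
    buffer_radius <- NULL
  }
  structure(
    list(
      name = name, source_category = source_category, aggregation = aggregation,
      buffer_radius = buffer_radius, expected_sign = expected_sign
    ),
    class = "predictor_spec"
  )
}

check_geometry_compat <- function(layer, aggregation) {
  needed <- switch(aggregation,
    count = "points", length = "lines", area = "polygons",
    NULL
  )
  if (!is.null(needed) && layer$type != needed) {
    abort_lur(
      "lur_type_error", "aggregation '%s' needs a %s layer; '%s' is %s",
      aggregation, needed, layer$category, layer$type
    )
  }
}

#' Aggregate a layer inside buffers around sites
#'
#' Counts points, sums clipped polyline length, or sums clipped polygon
#' area inside the closed disc of the given radius around each site.
#' Clipping is exact (chord solutions for lines, Green's-theorem circular
#' decomposition for polygons), not a centroid or rasterized approximation.
#'
#' @param layer a [feature_layer()].
#' @param sites data frame with numeric `x`, `y` columns (metres).
#' @param radius buffer radius in metres (> 0).
#' @param aggregation `"count"`, `"length"` or `"area"`; defaults to the
#'   natural aggregation for the layer's geometry type.
#' @return numeric vector, one value per site (count, metres, or square
#'   metres).
#' @export
buffer_aggregate <- function(layer, sites, radius,
                             aggregation = c("count", "length", "area")[
                               match(layer$type, c("points", "lines", "polygons"))
                             ]) {
  if (!is_scalar_number(radius) || radius <= 0) {
    abort_lur("lur_geometry_error", "radius must be a positive number")
  }
  check_geometry_compat(layer, aggregation)
  px <- sites$x
  py <- sites$y
  if (aggregation == "count") {
    g <- layer$geoms
    vapply(seq_along(px), function(i) {
      sum(sqrt((g[, 1] - px[i])^2 + (g[, 2] - py[i])^2) <= radius)
    }, numeric(1))
  } else if (aggregation == "length") {
    segs <- segment_table(layer$geoms)
    if (is.null(segs)) return(rep(0, length(px)))
    vapply(seq_along(px), function(i) {
      sum(chord_lengths_in_disc(
        segs[, "ax"], segs[, "ay"], segs[, "bx"], segs[, "by"],
        px[i], py[i], radius
      ))
    }, numeric(1))
  } else {
    bb <- geom_bboxes(layer$geoms)
    vapply(seq_along(px), function(i) {
      near <- which(bbox_near_disc(bb, px[i], py[i], radius))
      s <- 0
      for (j in near) {
        s <- s + disc_polygon_area(layer$geoms[[j]], px[i], py[i], radius)
      }
      s
    }, numeric(1))
  }
}

#' Distance to the nearest feature of a layer
#'
#' Exact Euclidean distance from each site to the nearest point, polyline,
#' or polygon boundary in the layer. A site lying on a feature gets 0.
#'
#' @inheritParams buffer_aggregate
#' @return numeric vector of metres, one per site.
#' @export
nearest_distance <- function(layer, sites) {
  if (n_features(layer) == 0L) {
    abort_lur("lur_empty_layer_error", "layer '%s' is empty: nearest distance undefined", layer$category)
  }
  vapply(seq_along(sites$x), function(i) {
    min_distance_to_geoms(sites$x[i], sites$y[i], layer$type, layer$geoms)
  }, numeric(1))
}

#' Inverse and inverse-squared distance transforms
#'
#' Computes `1 / max(d, floor)` and `1 / max(d, floor)^2`. The floor (1 m by
#' default) keeps the transforms finite when a site sits on a feature.
#'
#' @param d distances in metres (>= 0).
#' @param floor minimum distance in metres (> 0).
#' @return list with numeric vectors `inv` (1/m) and `inv_sq` (1/m^2).
#' @export
distance_transforms <- function(d, floor = 1) {
  if (!is_scalar_number(floor) || floor <= 0) {
    abort_lur("lur_geometry_error", "floor must be > 0")
  }
  if (any(d < 0, na.rm = TRUE)) abort_lur("lur_geometry_error", "distances must be >= 0")
  dd <- pmax(d, floor)
  list(inv = 1 / dd, inv_sq = 1 / dd^2)
}

#' Mean of raster cells inside a buffer
#'
#' Averages the values of all cells whose centres fall in the closed disc
#' of the given radius around each site. The raster must cover every buffer
#' entirely; a buffer poking outside the raster extent is an error naming
#' the offending site.
#'
#' @param raster an [ascii_grid()].
#' @param sites data frame with `x`, `y` (and optionally `site_id`).
#' @param radius buffer radius in metres.
#' @return numeric vector of per-site means.
#' @export
raster_buffer_mean <- function(raster, sites, radius) {
  if (!is_scalar_number(radius) || radius <= 0) {
    abort_lur("lur_geometry_error", "radius must be a positive number")
  }
  ctr <- grid_cell_centers(raster)
  xmin <- raster$xll
  xmax <- raster$xll + ncol(raster$values) * raster$cellsize
  ymin <- raster$yll
  ymax <- raster$yll + nrow(raster$values) * raster$cellsize
  ids <- sites$site_id %||% as.character(seq_along(sites$x))
  vapply(seq_along(sites$x), function(i) {
    x <- sites$x[i]
    y <- sites$y[i]
    if (x - radius < xmin || x + radius > xmax || y - radius < ymin || y + radius > ymax) {
      abort_lur(
        "lur_raster_extent_error",
        "buffer of %g m around site %s exits the raster extent", radius, ids[i]
      )
    }
    jj <- which(abs(ctr$x - x) <= radius)
    ii <- which(abs(ctr$y - y) <= radius)
    dx2 <- outer(ctr$y[ii], ctr$x[jj], function(cy, cx) (cx - x)^2 + (cy - y)^2)
    vals <- raster$values[ii, jj, drop = FALSE]
    mean(vals[dx2 <= radius^2])
  }, numeric(1))
}

#' Build the sites-by-predictors matrix
#'
#' Dispatches each [predictor_spec()] to the corresponding aggregation and
#' assembles the full predictor matrix with per-column spec metadata
#' (source, radius, transform, expected sign) carried forward for the
#' sign-constrained selection step.
#'
#' @param specs list of [predictor_spec()] objects (unique names).
#' @param layers named list of [feature_layer()] objects.
#' @param sites data frame with `site_id`, `x`, `y`.
#' @param raster an [ascii_grid()] for `raster_mean` specs (or `NULL`).
#' @param distance_floor floor in metres for inverse-distance transforms.
#' @return a `predictor_matrix`: list with `values` (numeric matrix, rows =
#'   sites), `specs` (named list of specs) and `site_id`.
#' @export
build_predictor_matrix <- function(specs, layers, sites, raster = NULL,
                                   distance_floor = 1) {
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort_lur("lur_spec_error", "duplicate predictor names: %s", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  cols <- lapply(specs, function(sp) {
    if (sp$aggregation == "raster_mean") {
      if (is.null(raster)) abort_lur("lur_missing_layer_error", "spec %s needs a raster, none supplied", sp$name)
      return(raster_buffer_mean(raster, sites, sp$buffer_radius))
    }
    layer <- layers[[sp$source_category]]
    if (is.null(layer)) {
      abort_lur("lur_missing_layer_error", "layer category '%s' (spec %s) is missing", sp$source_category, sp$name)
    }
    switch(sp$aggregation,
      count = ,
      length = ,
      area = buffer_aggregate(layer, sites, sp$buffer_radius, sp$aggregation),
      distance = nearest_distance(layer, sites),
      inverse_distance = distance_transforms(nearest_distance(layer, sites), distance_floor)$inv,
      inverse_sq_distance = distance_transforms(nearest_distance(layer, sites), distance_floor)$inv_sq
    )
  })
  values <- do.call(cbind, cols)
  colnames(values) <- nm
  rownames(values) <- as.character(sites$site_id %||% seq_len(nrow(values)))
  structure(
    list(values = values, specs = stats::setNames(specs, nm), site_id = rownames(values)),
    class = "predictor_matrix"
  )
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat(sprintf(
    "<predictor_matrix> %d sites x %d predictors\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Default buffered-predictor specs for a set of layers
#'
#' Expands each vector layer into the six canonical buffer aggregations
#' plus, for proximity layers, inverse and inverse-squared distance terms,
#' and each raster tag into the six canonical raster-mean radii — mirroring
#' the classical LUR predictor taxonomy (roads, transit, local point
#' sources, dwellings, land use, vegetation index).
#'
#' @param layers named list of [feature_layer()] objects.
#' @param raster_tag name stem used for raster-mean columns (default "NDVI").
#' @param include_raster add raster-mean specs.
#' @param distance_for categories that also get inverse-distance terms
#'   (default: all point and line layers).
#' @return list of [predictor_spec()] objects.
#' @export
default_predictor_specs <- function(layers, raster_tag = "NDVI",
                                    include_raster = TRUE,
                                    distance_for = NULL) {
  stems <- c(
    major_road = "MAJROAD", road = "ROAD", taxi_route = "TAXI",
    bus_route = "BUS_RTE", bus_stop = "BUS_ST", rail = "RAIL",
    train_station = "TRAINSTAT", airport = "AIR", burn_site = "BURN",
    grill = "GRILL", construction = "CONSTRUCTION",
    refuse_station = "REFTSTAT", dwelling = "ALLDWELL", coast = "COAST",
    landuse_residential = "LU_RESID", landuse_commercial = "LU_COMM",
    landuse_industrial = "LU_INDUS", landuse_open_space = "LU_OPEN",
    landuse_vegetation = "LU_VEG", landuse_water = "LU_WATER",
    landuse_public = "LU_PUBLIC", landuse_transport = "LU_TRANSP",
    landuse_restaurant = "LU_REST"
  )
  specs <- list()
  for (layer in layers) {
    stem <- if (layer$category %in% names(stems)) stems[[layer$category]] else toupper(layer$category)
    agg <- switch(layer$type, points = "count", lines = "length", polygons = "area")
    for (r in VECTOR_RADII) {
      specs[[length(specs) + 1L]] <- predictor_spec(
        paste0(stem, "_", r), layer$category, agg, r, layer$expected_sign
      )
    }
    want_d <- if (is.null(distance_for)) layer$type != "polygons" else layer$category %in% distance_for
    if (want_d) {
      specs[[length(specs) + 1L]] <- predictor_spec(
        paste0(stem, "_d_inv"), layer$category, "inverse_distance",
        expected_sign = layer$expected_sign
      )
      specs[[length(specs) + 1L]] <- predictor_spec(
        paste0(stem, "_d_inv2"), layer$category, "inverse_sq_distance",
        expected_sign = layer$expected_sign
      )
    }
  }
  if (include_raster) {
    for (r in RASTER_RADII) {
      specs[[length(specs) + 1L]] <- predictor_spec(
        paste0(raster_tag, "_", r), "raster", "raster_mean", r, "-"
      )
    }
  }
  specs
}

spec_to_list <- function(sp) {
  list(
    name = sp$name, source_category = sp$source_category,
    aggregation = sp$aggregation,
    buffer_radius = sp$buffer_radius, expected_sign = sp$expected_sign
  )
}

#' Write / read a predictor matrix as CSV plus a JSON spec sidecar
#'
#' @param pm a `predictor_matrix`.
#' @param csv_path CSV path for the values (first column `site_id`).
#' @param json_path sidecar path mapping column name to its spec; defaults
#'   to the CSV path with extension `.json`.
#' @return paths invisibly (write) or a `predictor_matrix` (read).
#' @export
write_predictor_matrix <- function(pm, csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- data.frame(site_id = pm$site_id, pm$values, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(lapply(pm$specs, spec_to_list), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

#' @rdname write_predictor_matrix
#' @export
read_predictor_matrix <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::fromJSON(json_path, simplifyVector = FALSE)
  specs <- lapply(meta, function(m) {
    predictor_spec(m$name, m$source_category, m$aggregation,
      m$buffer_radius %||% NULL, m$expected_sign,
      allow_any_radius = TRUE
    )
  })
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df$site_id)
  structure(
    list(values = values, specs = stats::setNames(specs, names(meta)), site_id = rownames(values)),
    class = "predictor_matrix"
  )
}
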