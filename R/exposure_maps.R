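# Exposure surfaces: apply a fitted model at arbitrary receptor points or
# over a regular grid. Receptor predictors are extracted with the exact
# same geo_features operations used at the monitoring sites — never
# interpolated from a previously computed grid — so there is no hidden
# approximation layer. Negative predictions clamp to the physical floor 0.

#' Predict concentrations at receptor points
#'
#' Builds only the fit's term columns via the buffer/ distance/ raster
#' operations, applies `intercept + sum(coef * value)`, and clamps negative
#' results to 0 with a flag.
#'
#' @param fit a `lur_fit`.
#' @param receptors data frame with `x`, `y` (metres) and optionally
#'   `receptor_id`.
#' @param layers named list of [feature_layer()] objects covering every
#'   term's source category.
#' @param raster an [ascii_grid()] if the fit uses raster-mean terms.
#' @param distance_floor floor for inverse-distance terms, metres.
#' @return data frame `receptor_id, x, y, pollutant, season, value_ugm3,
#'   clamped`.
#' @export
predict_points <- function(fit, receptors, layers, raster = NULL, distance_floor = 1) {
  stopifnot(inherits(fit, "lur_fit"))
  receptors$receptor_id <- receptors$receptor_id %||% sprintf("R%04d", seq_len(nrow(receptors)))
  terms <- fit$terms$name
  value <- if (length(terms) == 0L) {
    rep(fit$intercept, nrow(receptors))
  } else {
    for (t in terms) {
      sp <- fit$specs[[t]]
      if (is.null(sp)) abort_lur("lur_predict_error", "fit carries no spec for term %s", t)
      if (sp$aggregation != "raster_mean" && is.null(layers[[sp$source_category]])) {
        abort_lur(
          "lur_predict_error", "missing source layer '%s' for term %s",
          sp$source_category, t
        )
      }
      if (sp$aggregation == "raster_mean" && is.null(raster)) {
        abort_lur("lur_predict_error", "missing raster for term %s", t)
      }
    }
    sites <- data.frame(site_id = receptors$receptor_id, x = receptors$x, y = receptors$y)
    X <- build_predictor_matrix(unname(fit$specs[terms]), layers, sites, raster,
      distance_floor = distance_floor
    )
    fit$intercept + as.numeric(X$values[, terms, drop = FALSE] %*% fit$terms$coefficient)
  }
  data.frame(
    receptor_id = receptors$receptor_id, x = receptors$x, y = receptors$y,
    pollutant = fit$pollutant, season = fit$season,
    value_ugm3 = pmax(0, value), clamped = value < 0,
    stringsAsFactors = FALSE
  )
}

#' Predict an exposure surface over a regular grid
#'
#' Runs [predict_points()] at every cell centre of a `cell_size` grid over
#' the given bounding box and returns the surface plus the count of cells
#' clamped at 0.
#'
#' @param fit a `lur_fit`.
#' @param layers,raster,distance_floor as in [predict_points()].
#' @param cell_size grid resolution in metres (25 m default — the smallest
#'   vector buffer).
#' @param bbox `c(xmin, ymin, xmax, ymax)` of the prediction region.
#' @return a `prediction_grid`: list with `grid` (an [ascii_grid()]),
#'   `truncated` (count of clamped cells), `pollutant`, `season`.
#' @export
predict_grid <- function(fit, layers, raster = NULL, cell_size = 25,
                         bbox, distance_floor = 1) {
  width <- bbox[3] - bbox[1]
  height <- bbox[4] - bbox[2]
  if (!is_scalar_number(cell_size) || cell_size <= 0 || cell_size > width || cell_size > height) {
    abort_lur("lur_grid_error", "cell_size must be positive and no larger than the study area")
  }
  nx <- floor(width / cell_size)
  ny <- floor(height / cell_size)
  cx <- bbox[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- bbox[2] + (seq_len(ny) - 0.5) * cell_size
  pts <- expand.grid(x = cx, y = cy)
  pred <- predict_points(fit,
    data.frame(receptor_id = sprintf("C%06d", seq_len(nrow(pts))), x = pts$x, y = pts$y),
    layers, raster,
    distance_floor = distance_floor
  )
  # expand.grid varies x fastest: row r of the matrix is the (ny - r + 1)-th
  # y band so that row 1 is the northernmost (ESRI convention).
  m <- matrix(pred$value_ugm3, nrow = ny, ncol = nx, byrow = TRUE)[ny:1, , drop = FALSE]
  structure(
    list(
      grid = ascii_grid(m, xll = bbox[1], yll = bbox[2], cellsize = cell_size),
      truncated = sum(pred$clamped),
      pollutant = fit$pollutant, season = fit$season
    ),
    class = "prediction_grid"
  )
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf(
    "<prediction_grid> %s / %s, %d x %d cells, %d clamped at 0\n",
    x$pollutant, x$season, nrow(x$grid$values), ncol(x$grid$values), x$truncated
  ))
  invisible(x)
}

#' Export a prediction grid as ESRI ASCII raster and a rendered image
#'
#' @param pgrid a `prediction_grid`.
#' @param asc_path raster output path.
#' @param png_path optional image output path (`NULL` skips rendering).
#' @return paths, invisibly.
#' @export
write_prediction_grid <- function(pgrid, asc_path, png_path = NULL) {
  write_ascii_grid(pgrid$grid, asc_path)
  if (!is.null(png_path)) {
    g <- pgrid$grid
    grDevices::png(png_path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    ctr <- grid_cell_centers(g)
    graphics::image(
      x = ctr$x, y = rev(ctr$y), z = t(g$values[nrow(g$values):1, , drop = FALSE]),
      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
      xlab = "x (m)", ylab = "y (m)",
      main = sprintf("Predicted %s, %s (ug/m3)", pgrid$pollutant, pgrid$season),
      useRaster = TRUE, asp = 1
    )
  }
  invisible(c(asc_path, png_path))
}

#' Write receptor predictions as CSV
#'
#' Columns: `receptor_id, x, y, pollutant, season, value_ugm3, clamped`.
#'
#' @param pred output of [predict_points()].
#' @param path CSV path.
#' @return path, invisibly.
#' @export
write_receptor_predictions <- function(pred, path) {
  utils::write.csv(pred, path, row.names = FALSE)
  invisible(path)
}
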