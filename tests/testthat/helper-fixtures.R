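# Shared fixtures: a small, fast study configuration and simple layers
# built in code. Nothing is read from disk.

tiny_config <- function(seed = 42, n_sites = 24, weekly_capacity = 5, ...) {
  study_config(
    area_width = 1600, area_height = 1200, seed = seed, n_sites = n_sites,
    weekly_capacity = weekly_capacity, ...
  )
}

# A three-segment L-shaped polyline layer.
l_line_layer <- function(category = "major_road", sign = "+") {
  feature_layer(
    category, "lines",
    list(rbind(c(0, 0), c(100, 0), c(100, 100)), rbind(c(-50, 40), c(200, 40))),
    sign
  )
}

unit_sites <- function(xy) {
  data.frame(site_id = sprintf("S%02d", seq_len(nrow(xy))), x = xy[, 1], y = xy[, 2])
}

# Predictor matrix built directly from raw columns (bypasses geometry) for
# selection/validation tests: each column gets a declared expected sign.
raw_matrix <- function(X, signs) {
  specs <- lapply(colnames(X), function(nm) {
    predictor_spec(nm, "synthetic", "count", 100, signs[[nm]])
  })
  structure(
    list(
      values = as.matrix(X),
      specs = stats::setNames(specs, colnames(X)),
      site_id = rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
    ),
    class = "predictor_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
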