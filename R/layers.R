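# Vector layers and the raster grid. A feature_layer is the package's
# GIS container: a homogeneous set of point / polyline / polygon features
# with a category tag and the a-priori expected direction of effect of
# predictors built from it. Geometry is stored as plain numeric matrices
# (points: one n x 2 matrix; lines/polygons: a list of vertex matrices),
# which keeps every downstream operation a direct vectorized computation.

#' Construct a feature layer
#'
#' @param category layer category tag, e.g. `"major_road"`, `"grill"`.
#' @param type one of `"points"`, `"lines"`, `"polygons"`.
#' @param geoms for `"points"` an n x 2 matrix of coordinates; otherwise a
#'   list of two-column vertex matrices (polygon rings may be open; they are
#'   closed on use).
#' @param expected_sign `"+"` or `"-"`: the a-priori direction of effect on
#'   pollutant concentration of predictors derived from this layer.
#' @param names optional per-feature names.
#' @return a `feature_layer` object.
#' @export
feature_layer <- function(category, type = c("points", "lines", "polygons"),
                          geoms, expected_sign = "+", names = NULL) {
  type <- match.arg(type)
  if (type == "points") {
    geoms <- as.matrix(geoms)
    if (ncol(geoms) != 2L) abort_lur("lur_layer_error", "point layer needs an n x 2 matrix")
    n <- nrow(geoms)
  } else {
    if (!is.list(geoms)) abort_lur("lur_layer_error", "%s layer needs a list of vertex matrices", type)
    geoms <- lapply(geoms, function(m) {
      m <- as.matrix(m)
      storage.mode(m) <- "double"
      m
    })
    n <- length(geoms)
  }
  if (!expected_sign %in% c("+", "-")) {
    abort_lur("lur_layer_error", "expected_sign must be '+' or '-'")
  }
  structure(
    list(
      category = category, type = type, geoms = geoms,
      expected_sign = expected_sign,
      names = names %||% paste0(category, "_", seq_len(n))
    ),
    class = "feature_layer"
  )
}

#' @export
print.feature_layer <- function(x, ...) {
  n <- if (x$type == "points") nrow(x$geoms) else length(x$geoms)
  cat(sprintf(
    "<feature_layer> category=%s type=%s features=%d expected_sign=%s\n",
    x$category, x$type, n, x$expected_sign
  ))
  invisible(x)
}

n_features <- function(layer) {
  if (layer$type == "points") nrow(layer$geoms) else length(layer$geoms)
}

#' Construct a regular raster grid
#'
#' Row 1 of `values` is the northernmost row (ESRI ASCII convention). Cell
#' centres are at `xll + (col - 0.5) * cellsize` and
#' `yll + (nrow - row + 0.5) * cellsize`.
#'
#' @param values numeric matrix of cell values.
#' @param xll,yll coordinates of the lower-left corner of the grid (metres).
#' @param cellsize cell edge length in metres.
#' @return an `ascii_grid` object.
#' @export
ascii_grid <- function(values, xll, yll, cellsize) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize),
    class = "ascii_grid"
  )
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf(
    "<ascii_grid> %d rows x %d cols, cellsize %g m, origin (%g, %g)\n",
    nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll
  ))
  invisible(x)
}

grid_cell_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  list(
    x = grid$xll + (seq_len(nc) - 0.5) * grid$cellsize,
    y = grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  )
}

#' Write / read a raster as an ESRI ASCII grid file
#'
#' @param grid an [ascii_grid()].
#' @param path file path.
#' @param nodata NODATA sentinel written for `NA` cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns an [ascii_grid()].
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$xll),
    sprintf("yllcorner %.6f", grid$yll),
    sprintf("cellsize %.6f", grid$cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  utils::write.table(v, con,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  if (nrow(v) != h[["nrows"]] || ncol(v) != h[["ncols"]]) {
    abort_lur("lur_io_error", "grid body does not match header dimensions in %s", path)
  }
  v[v == h[["nodata_value"]]] <- NA_real_
  ascii_grid(v, h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]])
}

# ---- GeoJSON ---------------------------------------------------------------

geom_to_geojson <- function(type, g) {
  if (type == "points") {
    list(type = "Point", coordinates = c(g[1], g[2]))
  } else if (type == "lines") {
    list(type = "LineString", coordinates = unname(lapply(seq_len(nrow(g)), function(i) c(g[i, 1], g[i, 2]))))
  } else {
    ring <- close_ring(g)
    list(type = "Polygon", coordinates = list(
      unname(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
    ))
  }
}

#' Write / read feature layers as GeoJSON FeatureCollections
#'
#' One file per layer, named `<category>.geojson`, each feature carrying
#' `category` and `name` properties plus the layer-level `expected_sign`.
#' Coordinates are local planar metres, not longitude/latitude.
#'
#' @param layers named list of [feature_layer()] objects.
#' @param dir output / input directory.
#' @return `write_layers_geojson` returns the file paths invisibly;
#'   `read_layers_geojson` returns a named list of layers.
#' @export
write_layers_geojson <- function(layers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(layers, function(layer) {
    feats <- if (layer$type == "points") {
      lapply(seq_len(nrow(layer$geoms)), function(i) layer$geoms[i, ])
    } else {
      layer$geoms
    }
    features <- lapply(seq_along(feats), function(i) {
      list(
        type = "Feature",
        properties = list(
          category = layer$category, name = layer$names[[i]],
          expected_sign = layer$expected_sign
        ),
        geometry = geom_to_geojson(layer$type, feats[[i]])
      )
    })
    fc <- list(type = "FeatureCollection", features = features)
    path <- file.path(dir, paste0(layer$category, ".geojson"))
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_layers_geojson
#' @export
read_layers_geojson <- function(dir) {
  files <- list.files(dir, pattern = "\\.geojson$", full.names = TRUE)
  layers <- lapply(files, function(path) {
    fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(fc$features) == 0L) abort_lur("lur_io_error", "empty FeatureCollection: %s", path)
    gtype <- fc$features[[1]]$geometry$type
    type <- switch(gtype,
      Point = "points", LineString = "lines", Polygon = "polygons",
      abort_lur("lur_io_error", "unsupported geometry type %s in %s", gtype, path)
    )
    coords <- lapply(fc$features, function(f) f$geometry$coordinates)
    geoms <- if (type == "points") {
      do.call(rbind, lapply(coords, function(xy) c(xy[[1]], xy[[2]])))
    } else if (type == "lines") {
      lapply(coords, function(cl) do.call(rbind, lapply(cl, function(xy) c(xy[[1]], xy[[2]]))))
    } else {
      lapply(coords, function(cl) do.call(rbind, lapply(cl[[1]], function(xy) c(xy[[1]], xy[[2]]))))
    }
    p1 <- fc$features[[1]]$properties
    feature_layer(
      category = p1$category, type = type, geoms = geoms,
      expected_sign = p1$expected_sign %||% "+",
      names = vapply(fc$features, function(f) as.character(f$properties$name), character(1))
    )
  })
  stats::setNames(layers, vapply(layers, `[[`, character(1), "category"))
}
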