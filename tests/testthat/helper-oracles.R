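# Independent oracles: deliberately different mechanisms from the package
# implementations (optimizer-based distances, densified resampling for
# clipped lengths, grid scans with a standalone ray-casting test for
# areas, explicit per-cell loops for raster means).

# Distance to a segment by 1-D minimization over the parameter t.
oracle_segment_distance <- function(px, py, a, b) {
  f <- function(t) {
    q <- a + t * (b - a)
    sqrt((px - q[1])^2 + (py - q[2])^2)
  }
  opt <- stats::optimize(f, c(0, 1), tol = 1e-12)
  min(opt$objective, f(0), f(1))
}

oracle_min_distance <- function(px, py, geoms) {
  best <- Inf
  for (m in geoms) {
    for (i in seq_len(nrow(m) - 1L)) {
      best <- min(best, oracle_segment_distance(px, py, m[i, ], m[i + 1L, ]))
    }
  }
  best
}

# Clipped polyline length by dense resampling: midpoints of `step`-long
# slivers counted inside the disc, times step.
oracle_clipped_length <- function(geoms, cx, cy, r, step = 0.05) {
  total <- 0
  for (m in geoms) {
    for (i in seq_len(nrow(m) - 1L)) {
      a <- m[i, ]
      b <- m[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      if (len == 0) next
      k <- max(1L, ceiling(len / step))
      t <- (seq_len(k) - 0.5) / k
      qx <- a[1] + t * (b[1] - a[1])
      qy <- a[2] + t * (b[2] - a[2])
      total <- total + sum((qx - cx)^2 + (qy - cy)^2 <= r^2) * len / k
    }
  }
  total
}

# Standalone even-odd ray casting (horizontal ray to +x).
oracle_point_in_polygon <- function(px, py, ring) {
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]
    y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]
    y2 <- ring[i + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py))
    xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, crosses & (px < xint))
  }
  inside
}

# Disc-polygon intersection area by scanning a fine grid over the disc's
# bounding box.
oracle_disc_polygon_area <- function(ring, cx, cy, r, cell = 0.5) {
  xs <- seq(cx - r + cell / 2, cx + r, by = cell)
  ys <- seq(cy - r + cell / 2, cy + r, by = cell)
  g <- expand.grid(x = xs, y = ys)
  in_disc <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  hits <- oracle_point_in_polygon(g$x[in_disc], g$y[in_disc], ring)
  sum(hits) * cell^2
}

oracle_raster_mean <- function(raster, x, y, r) {
  vals <- c()
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cxx <- raster$xll + (j - 0.5) * raster$cellsize
      cyy <- raster$yll + (nr - i + 0.5) * raster$cellsize
      if ((cxx - x)^2 + (cyy - y)^2 <= r^2) vals <- c(vals, raster$values[i, j])
    }
  }
  mean(vals)
}

# Random simple (convex) polygon: convex hull of uniform points.
random_convex_polygon <- function(n = 8, xr = c(-100, 100), yr = c(-100, 100)) {
  pts <- cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]))
  hull <- grDevices::chull(pts)
  pts[hull, , drop = FALSE]
}

random_polyline <- function(n = 5, xr = c(-150, 150), yr = c(-150, 150)) {
  cbind(stats::runif(n, xr[1], xr[2]), stats::runif(n, yr[1], yr[2]))
}

# Moran's I by literal double loop over the formula.
oracle_morans_i <- function(z, coords, floor = 1) {
  z <- z - mean(z)
  n <- length(z)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        w[i, j] <- 1 / max(d, floor)
      }
    }
  }
  w <- w / rowSums(w)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  }
  (n / sum(w)) * num / sum(z^2)
}
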