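# Planar Euclidean geometry primitives (metres). All buffer predictors in
# this package reduce to three exact operations on a closed disc:
#   * point-in-disc tests                  -> counts
#   * segment-disc chord clipping          -> clipped polyline length
#   * disc-polygon intersection area       -> clipped polygon area
# plus exact point-to-segment distances for the proximity predictors.
# Coordinates live in a local Cartesian system; no geodesy anywhere.

#' Distance from points to line segments
#'
#' Exact Euclidean distance from one or more points to one or more segments
#' (vectors are recycled as usual). The distance to a segment is the distance
#' to its orthogonal projection when the foot falls inside the segment, else
#' to the nearer endpoint.
#'
#' @param px,py point coordinates (metres).
#' @param ax,ay,bx,by segment endpoint coordinates.
#' @return numeric vector of distances, metres.
#' @export
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Flatten a list of polyline/ring vertex matrices into one segment table.
segment_table <- function(geoms) {
  parts <- lapply(geoms, function(m) {
    n <- nrow(m)
    if (n < 2L) return(NULL)
    cbind(ax = m[-n, 1], ay = m[-n, 2], bx = m[-1, 1], by = m[-1, 2])
  })
  do.call(rbind, parts)
}

# Length of each segment falling inside the closed disc of radius r at
# (cx, cy). Solves |A + t(B - A) - C|^2 = r^2 and clips the root interval
# to [0, 1]; tangency contributes zero length.
chord_lengths_in_disc <- function(ax, ay, bx, by, cx, cy, r) {
  dx <- bx - ax
  dy <- by - ay
  fx <- ax - cx
  fy <- ay - cy
  a <- dx * dx + dy * dy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  out <- numeric(length(ax))
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    out[ok] <- pmax(0, t2 - t1) * sqrt(a[ok])
  }
  out
}

#' Shoelace area of a polygon ring
#'
#' @param ring two-column matrix of vertices (closed or open ring).
#' @return unsigned area in square metres.
#' @export
polygon_area <- function(ring) {
  ring <- close_ring(ring)
  n <- nrow(ring)
  x <- ring[, 1]
  y <- ring[, 2]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

close_ring <- function(ring) {
  if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L) {
    abort_lur("lur_geometry_error", "a polygon ring needs a 2-column matrix with >= 3 vertices")
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# Exact area of the intersection of a simple polygon with the closed disc of
# radius r centred at (cx, cy), by Green's-theorem edge decomposition: each
# edge is split at its circle crossings; sub-segments inside the disc
# contribute a triangle term cross(P,Q)/2, sub-segments outside contribute
# the circular sector swept between their endpoint directions, r^2 * dtheta / 2.
# Valid for simple (non self-intersecting) rings of either orientation.
disc_polygon_area <- function(ring, cx, cy, r) {
  ring <- close_ring(ring)
  px <- ring[, 1] - cx
  py <- ring[, 2] - cy
  n <- length(px) - 1L
  r2 <- r * r
  # fast path: every vertex inside the disc -> plain shoelace area
  if (max(px * px + py * py) <= r2) {
    return(abs(sum(px[-(n + 1L)] * py[-1] - px[-1] * py[-(n + 1L)])) / 2)
  }
  total <- 0
  for (i in seq_len(n)) {
    ax <- px[i]
    ay <- py[i]
    dx <- px[i + 1L] - ax
    dy <- py[i + 1L] - ay
    a <- dx * dx + dy * dy
    if (a == 0) next
    b <- 2 * (ax * dx + ay * dy)
    cc <- ax * ax + ay * ay - r2
    # breakpoints 0 <= t1 <= t2 <= 1 come ordered from the quadratic roots
    ts <- 0
    disc <- b * b - 4 * a * cc
    if (disc > 0) {
      sq <- sqrt(disc)
      t1 <- (-b - sq) / (2 * a)
      t2 <- (-b + sq) / (2 * a)
      if (t1 > 0 && t1 < 1) ts <- c(ts, t1)
      if (t2 > 0 && t2 < 1) ts <- c(ts, t2)
    }
    ts <- c(ts, 1)
    for (k in seq_len(length(ts) - 1L)) {
      u <- ts[k]
      v <- ts[k + 1L]
      p1x <- ax + u * dx
      p1y <- ay + u * dy
      q1x <- ax + v * dx
      q1y <- ay + v * dy
      ms <- (u + v) / 2
      mx <- ax + ms * dx
      my <- ay + ms * dy
      cr <- p1x * q1y - p1y * q1x
      if (mx * mx + my * my <= r2) {
        total <- total + cr / 2
      } else {
        total <- total + r2 * atan2(cr, p1x * q1x + p1y * q1y) / 2
      }
    }
  }
  abs(total)
}

# Axis-aligned bounding boxes of a list of vertex matrices, one row each.
geom_bboxes <- function(geoms) {
  t(vapply(geoms, function(m) {
    c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
  }, numeric(4)))
}

# TRUE where the disc at (x, y, r) could intersect each bbox row.
bbox_near_disc <- function(bb, x, y, r) {
  dx <- pmax(0, pmax(bb[, 1] - x, x - bb[, 3]))
  dy <- pmax(0, pmax(bb[, 2] - y, y - bb[, 4]))
  dx * dx + dy * dy <= r * r
}

# Minimum distance from a single point to a geometry collection.
min_distance_to_geoms <- function(px, py, type, geoms) {
  if (type == "points") {
    return(min(sqrt((geoms[, 1] - px)^2 + (geoms[, 2] - py)^2)))
  }
  segs <- segment_table(geoms)
  if (is.null(segs)) abort_lur("lur_geometry_error", "layer has no segments")
  min(point_segment_distance(px, py, segs[, "ax"], segs[, "ay"], segs[, "bx"], segs[, "by"]))
}
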