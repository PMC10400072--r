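# Shared geometry and angle helpers.

#' Wrap angles into (-pi, pi]
#'
#' @param theta angle(s) in radians.
#' @return wrapped angle(s) in radians.
#' @keywords internal
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Wrap angles in degrees into (-180, 180]
#' @param deg angle(s) in degrees.
#' @keywords internal
wrap_deg <- function(deg) wrap_angle(deg * pi / 180) * 180 / pi

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Convert mm coordinates to pixel coordinates
#'
#' mm coordinates have the origin at the bottom-left of the arena with `y`
#' upward; pixel coordinates have `x` along the first array index and `y`
#' downward, with pixel centres at (i - 0.5, j - 0.5).
#'
#' @param x,y coordinates in mm.
#' @param px_per_mm imaging scale (px/mm).
#' @param arena_side arena side length in mm.
#' @return two-column matrix of pixel coordinates.
#' @export
mm_to_px <- function(x, y, px_per_mm, arena_side) {
  cbind(x = x * px_per_mm, y = (arena_side - y) * px_per_mm)
}

#' Convert pixel coordinates to mm coordinates
#' @param x,y pixel coordinates.
#' @inheritParams mm_to_px
#' @return two-column matrix of mm coordinates.
#' @export
px_to_mm <- function(x, y, px_per_mm, arena_side) {
  cbind(x = x / px_per_mm, y = arena_side - y / px_per_mm)
}

# Vectorised point-to-segment distance. Returns the distance and the
# normalised projection parameter t in [0, 1] for each query point.
point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) {
    d <- sqrt((px - x1)^2 + (py - y1)^2)
    return(list(dist = d, t = rep(0, length(px))))
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- x1 + t * dx
  qy <- y1 + t * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t)
}

# Ray-crossing point-in-polygon test (non-convex safe). poly is an n x 2
# matrix of vertices; returns logical vector for query points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Cumulative arc length of a polyline given as an n x 2 matrix.
arc_length <- function(pts) {
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(d))
}

# Resample a polyline to n points equally spaced in arc length.
resample_polyline <- function(pts, n) {
  s <- arc_length(pts)
  total <- s[length(s)]
  if (total == 0) {
    return(matrix(rep(pts[1, ], n), ncol = 2, byrow = TRUE))
  }
  target <- seq(0, total, length.out = n)
  cbind(approx(s, pts[, 1], xout = target, ties = "ordered")$y,
        approx(s, pts[, 2], xout = target, ties = "ordered")$y)
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  }
  invisible(x)
}
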