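# Posture estimation: head/tail keypoints on the body contour, the
# contour-halving spine, the midspine position and the body-bend angle.

# Discrete curvature score at every contour vertex: the exterior angle
# between the segments to the k-th neighbours on either side. High values
# mark sharp protrusions (body ends).
contour_curvature <- function(contour, k = NULL) {
  n <- nrow(contour)
  if (is.null(k)) k <- max(2L, round(n / 12))
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  v1 <- contour - contour[im, , drop = FALSE]
  v2 <- contour[ip, , drop = FALSE] - contour
  a1 <- atan2(v1[, 2], v1[, 1])
  a2 <- atan2(v2[, 2], v2[, 1])
  abs(wrap_angle(a2 - a1))
}

#' Estimate head and tail keypoints from a body contour
#'
#' Deterministic geometric estimator: the two body ends are the contour
#' vertices of locally maximal curvature separated by at least a third of
#' the perimeter. The head is the end better aligned with the momentum
#' vector, since larvae crawl head-first during runs; when momentum is
#' near zero the previous head/tail assignment is kept for temporal
#' consistency. On a near-circular contour, where curvature extremes are
#' indistinct, the previous posture is carried with low confidence.
#'
#' @param contour n x 2 matrix of ordered contour vertices (px, n >= 8).
#' @param previous the posture from the previous frame (or NULL).
#' @param momentum c(dx, dy) displacement per frame (px, image
#'   coordinates).
#' @param min_momentum below this speed (px/frame) the momentum cue is
#'   considered unreliable.
#' @return list with `head`, `tail` (px), `confidence` in [0, 1] and the
#'   vertex indices `head_idx`, `tail_idx`.
#' @export
estimate_head_tail <- function(contour, previous = NULL, momentum = c(0, 0),
                               min_momentum = 0.2) {
  stopifnot(is.matrix(contour), nrow(contour) >= 8)
  n <- nrow(contour)
  curv <- contour_curvature(contour)
  s <- arc_length(rbind(contour, contour[1, ]))
  perim <- s[length(s)]
  i1 <- which.max(curv)
  # second end: best curvature at arc distance >= perimeter/3 from i1
  ds <- pmin(abs(s[seq_len(n)] - s[i1]), perim - abs(s[seq_len(n)] - s[i1]))
  far <- which(ds >= perim / 3)
  if (length(far) == 0) {
    return(carry_posture(previous))
  }
  i2 <- far[which.max(curv[far])]

  # distinctness of the two ends relative to the contour's typical bend;
  # a circle has uniform curvature and yields a score near 1
  base <- median(curv)
  distinct <- min(curv[i1], curv[i2]) / max(base, 1e-6)
  if (distinct < 1.25) {
    return(carry_posture(previous))
  }

  e1 <- contour[i1, ]; e2 <- contour[i2, ]
  sp <- sqrt(sum(momentum^2))
  if (sp >= min_momentum) {
    u <- momentum / sp
    axis <- e1 - e2
    head_is_1 <- sum(axis * u) >= 0
  } else if (!is.null(previous) && !is.na(previous$head[1])) {
    d1 <- sum((e1 - previous$head)^2) + sum((e2 - previous$tail)^2)
    d2 <- sum((e2 - previous$head)^2) + sum((e1 - previous$tail)^2)
    head_is_1 <- d1 <= d2
  } else {
    head_is_1 <- TRUE
  }
  conf <- min(1, distinct / 3) * if (sp >= min_momentum) 1 else 0.7
  if (head_is_1) {
    list(head = e1, tail = e2, head_idx = i1, tail_idx = i2,
         confidence = conf)
  } else {
    list(head = e2, tail = e1, head_idx = i2, tail_idx = i1,
         confidence = conf)
  }
}

carry_posture <- function(previous) {
  if (is.null(previous)) {
    return(list(head = c(NA_real_, NA_real_), tail = c(NA_real_, NA_real_),
                head_idx = NA_integer_, tail_idx = NA_integer_,
                confidence = 0))
  }
  previous$confidence <- min(previous$confidence, 0.2)
  previous
}

#' Compute the spine, midspine and body bend from a contour
#'
#' The contour is split at the head and tail (snapped to the nearest
#' contour vertices) into the two body-side halves `c1` and `c2`. Both
#' halves are resampled to `n_points` by linear interpolation along arc
#' length, and spine point k is the midpoint of the equidistant pair
#' `(c1[k], c2[k])`. The midspine — the middle spine vertex — serves as a
#' refined position of the animal. The body bend is the angle at the
#' midspine between the mean tail-half direction into the midspine and
#' the mean head-half direction out of it: 0 deg = straight, sign
#' positive when the head half bends counter-clockwise (to the animal's
#' left in mm coordinates; note image coordinates have y down, so callers
#' working in mm flip the sign).
#'
#' @param contour n x 2 matrix of ordered contour vertices (px).
#' @param head,tail keypoint coordinates (px); must be distinct.
#' @param n_points number of spine points (odd keeps a unique midspine).
#' @return list with `spine` (n_points x 2, head first), `midspine`,
#'   `body_bend` (degrees) and the half-contours `c1`, `c2`.
#' @export
compute_spine <- function(contour, head, tail, n_points = 11) {
  stopifnot(is.matrix(contour), nrow(contour) >= 4, n_points >= 3)
  hi <- which.min((contour[, 1] - head[1])^2 + (contour[, 2] - head[2])^2)
  ti <- which.min((contour[, 1] - tail[1])^2 + (contour[, 2] - tail[2])^2)
  if (hi == ti) stop("head and tail snap to the same contour vertex",
                     call. = FALSE)
  n <- nrow(contour)
  idx1 <- if (hi <= ti) hi:ti else c(hi:n, 1:ti)
  idx2 <- if (ti <= hi) ti:hi else c(ti:n, 1:hi)
  c1 <- contour[idx1, , drop = FALSE]               # head -> tail, side 1
  c2 <- contour[rev(idx2), , drop = FALSE]          # head -> tail, side 2
  r1 <- resample_polyline(c1, n_points)
  r2 <- resample_polyline(c2, n_points)
  spine <- (r1 + r2) / 2
  mid_k <- ceiling(n_points / 2)
  midspine <- spine[mid_k, ]

  # mean directions of the tail half (into the midspine) and the head
  # half (from the midspine toward the head)
  head_dir <- spine[1, ] - midspine
  tail_dir <- midspine - spine[n_points, ]
  bend <- wrap_angle(atan2(head_dir[2], head_dir[1]) -
                     atan2(tail_dir[2], tail_dir[1]))
  list(spine = spine, midspine = midspine, body_bend = rad2deg(bend),
       c1 = r1, c2 = r2)
}
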