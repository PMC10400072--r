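# Frame-to-frame identity linking: weighted linking loss, greedy
# assignment, gap interpolation and collision detection/resolution.

#' Linking configuration
#'
#' Weights of the frame-to-frame linking loss
#' `L_ij = beta_r * D(r_i, r_j) + beta_p * D(p_i, p_j) + beta_a * D(a_i, a_j)`
#' where `r` is position (px), `p` momentum (px/frame), `a` contour area
#' (px^2) and `D` the Euclidean distance. The defaults balance the terms
#' at pixel scale; they can be adjusted for other animals or imaging
#' conditions.
#'
#' @param beta_r,beta_p,beta_a non-negative weights (not all zero).
#' @param max_loss assignment gate: pairs with loss above this stay
#'   unmatched.
#' @param interp_max_gap longest gap (frames) bridged by interpolation
#'   before a track is closed.
#' @param momentum_window frames over which momentum (mean displacement
#'   per frame) is computed.
#' @return an object of class `linking_config`.
#' @export
linking_config <- function(beta_r = 1, beta_p = 0.5, beta_a = 0.01,
                           max_loss = 30, interp_max_gap = 80,
                           momentum_window = 5) {
  stopifnot(beta_r >= 0, beta_p >= 0, beta_a >= 0,
            beta_r + beta_p + beta_a > 0,
            max_loss > 0, interp_max_gap >= 0, momentum_window >= 1)
  structure(list(beta_r = beta_r, beta_p = beta_p, beta_a = beta_a,
                 max_loss = max_loss, interp_max_gap = interp_max_gap,
                 momentum_window = as.integer(momentum_window)),
            class = "linking_config")
}

#' Create a track state
#'
#' @param id integer identity.
#' @param r position c(x, y) in px.
#' @param p momentum c(dx, dy) in px/frame.
#' @param a contour area in px^2.
#' @param last_seen frame index of the last observation.
#' @return an object of class `track_state` (a list).
#' @export
track_state <- function(id, r, p = c(0, 0), a = 0, last_seen = 1L) {
  structure(list(id = as.integer(id), r = as.numeric(r),
                 p = as.numeric(p), a = a,
                 last_seen = as.integer(last_seen)),
            class = "track_state")
}

#' Linking loss between a detection and a track
#'
#' `L_ij = beta_r * ||r_i - r_j|| + beta_p * ||p_i - p_j|| +
#'  beta_a * |a_i - a_j|`, where the detection momentum `p_i` is the
#' candidate displacement `centroid_i - r_j` and the area distance is the
#' 1-D Euclidean (absolute) difference.
#'
#' @param det a detection (list with `centroid` and `area`), e.g. from
#'   [extract_detections()].
#' @param track a [track_state()].
#' @param cfg a [linking_config()].
#' @return non-negative scalar loss.
#' @export
link_loss <- function(det, track, cfg) {
  dr <- det$centroid - track$r
  pi_cand <- dr                       # candidate displacement as momentum
  cfg$beta_r * sqrt(sum(dr^2)) +
    cfg$beta_p * sqrt(sum((pi_cand - track$p)^2)) +
    cfg$beta_a * abs(det$area - track$a)
}

#' Greedy identity assignment
#'
#' Assigns detections to tracks strictly greedily: the pair with the
#' lowest loss first, then the lowest loss among the remaining pairs, and
#' so on. This is deliberately not a globally optimal assignment. Pairs
#' with loss above `cfg$max_loss` are left unmatched. Ties break toward
#' the lower track id, then the lower detection index, so assignment is
#' deterministic.
#'
#' @param dets list of detections.
#' @param tracks list of [track_state()]s.
#' @param cfg a [linking_config()].
#' @return list with `matches` (data.frame `track_idx`, `det_idx`,
#'   `loss`), `unmatched_tracks` and `unmatched_dets` (index vectors).
#' @export
assign_identities <- function(dets, tracks, cfg) {
  nt <- length(tracks); nd <- length(dets)
  empty <- data.frame(track_idx = integer(0), det_idx = integer(0),
                      loss = numeric(0))
  if (nt == 0 || nd == 0) {
    return(list(matches = empty, unmatched_tracks = seq_len(nt),
                unmatched_dets = seq_len(nd)))
  }
  loss <- matrix(0, nt, nd)
  for (i in seq_len(nt)) {
    for (j in seq_len(nd)) loss[i, j] <- link_loss(dets[[j]], tracks[[i]], cfg)
  }
  ids <- vapply(tracks, function(tr) tr$id, integer(1))
  ord <- order(as.vector(loss), rep(ids, nd),
               rep(seq_len(nd), each = nt))
  t_used <- rep(FALSE, nt); d_used <- rep(FALSE, nd)
  m_t <- integer(0); m_d <- integer(0); m_l <- numeric(0)
  for (k in ord) {
    i <- (k - 1L) %% nt + 1L
    j <- (k - 1L) %/% nt + 1L
    if (t_used[i] || d_used[j]) next
    if (loss[i, j] > cfg$max_loss) break   # ordered, so all later exceed too
    t_used[i] <- TRUE; d_used[j] <- TRUE
    m_t <- c(m_t, i); m_d <- c(m_d, j); m_l <- c(m_l, loss[i, j])
  }
  list(matches = data.frame(track_idx = m_t, det_idx = m_d, loss = m_l),
       unmatched_tracks = which(!t_used),
       unmatched_dets = which(!d_used))
}

#' Linearly interpolate a positional gap
#'
#' Fills the frames strictly between two flanking observations by linear
#' interpolation; the filled frames are flagged `interpolated`. Larvae
#' crawl well below a body length per frame at 10 Hz, so significant
#' behaviour is unlikely inside short gaps and linear interpolation is
#' sufficient to rebuild the trajectory; interpolated frames are excluded
#' from turn detection downstream.
#'
#' @param track a data.frame with columns `frame`, `x`, `y` containing
#'   the flanking observations (and any others).
#' @param gap integer vector of the missing frame indices (may be empty).
#' @param max_gap gaps longer than this raise an error (the caller should
#'   close the track instead).
#' @return data.frame with columns `frame`, `x`, `y`, `interpolated` for
#'   the gap frames (zero rows for an empty gap).
#' @export
interpolate_gaps <- function(track, gap, max_gap = Inf) {
  if (length(gap) == 0) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      interpolated = logical(0)))
  }
  if (length(gap) > max_gap) {
    stop("gap of ", length(gap), " frames exceeds max_gap = ", max_gap,
         call. = FALSE)
  }
  f0 <- max(track$frame[track$frame < min(gap)])
  f1 <- min(track$frame[track$frame > max(gap)])
  if (!is.finite(f0) || !is.finite(f1)) {
    stop("gap is not flanked by observations", call. = FALSE)
  }
  p0 <- track[track$frame == f0, c("x", "y")]
  p1 <- track[track$frame == f1, c("x", "y")]
  w <- (gap - f0) / (f1 - f0)
  data.frame(frame = gap,
             x = p0$x + w * (p1$x - p0$x),
             y = p0$y + w * (p1$y - p0$y),
             interpolated = TRUE)
}

#' Detect collision events
#'
#' A collision opens when the predicted positions (`r + p`) of two or
#' more tracks fall within a single detection whose area exceeds the
#' maximum single-animal area — the signature of contours stacked into
#' one large contour.
#'
#' @param dets list of detections (typically those above the single-animal
#'   size gate).
#' @param tracks list of [track_state()]s.
#' @param max_single_area largest area a single animal can have (px^2).
#' @param slack bounding-box slack in px when testing containment.
#' @return list of collision events: each a list with `det_idx`,
#'   `participants` (track indices), `ids` (track ids) and `frame`.
#' @export
detect_collision <- function(dets, tracks, max_single_area, slack = 3) {
  events <- list()
  if (length(dets) == 0 || length(tracks) < 2) return(events)
  pred <- t(vapply(tracks, function(tr) tr$r + tr$p, numeric(2)))
  for (j in seq_along(dets)) {
    d <- dets[[j]]
    if (d$area <= max_single_area) next
    bb <- d$bbox
    inside <- which(pred[, 1] >= bb[1] - 1 - slack &
                    pred[, 1] <= bb[2] + slack &
                    pred[, 2] >= bb[3] - 1 - slack &
                    pred[, 2] <= bb[4] + slack)
    if (length(inside) >= 2) {
      events[[length(events) + 1]] <- list(
        det_idx = j, participants = inside,
        ids = vapply(tracks[inside], function(tr) tr$id, integer(1)),
        frame = d$frame)
    }
  }
  events
}

# paint a logical window into a canvas at integer offset; returns canvas
paint_mask <- function(canvas, win, off) {
  i0 <- off[1] + 1L; j0 <- off[2] + 1L
  i1 <- i0 + nrow(win) - 1L; j1 <- j0 + ncol(win) - 1L
  ci0 <- max(1L, i0); cj0 <- max(1L, j0)
  ci1 <- min(nrow(canvas), i1); cj1 <- min(ncol(canvas), j1)
  if (ci0 > ci1 || cj0 > cj1) return(canvas)
  sub <- win[(ci0 - i0 + 1L):(ci1 - i0 + 1L),
             (cj0 - j0 + 1L):(cj1 - j0 + 1L), drop = FALSE]
  canvas[ci0:ci1, cj0:cj1] <- canvas[ci0:ci1, cj0:cj1] | sub
  canvas
}

#' Resolve a collision by contour-translation optimisation
#'
#' Each participant's last pre-collision contour mask is translated so
#' that the union of the translated masks best matches the merged
#' contour. Translations are initialised from each participant's momentum
#' and refined by integer hill-climbing over a +/-2 px neighbourhood per
#' epoch, maximising intersection-over-union, for at most `max_epochs`
#' epochs. The translated centroids are reported as the participants'
#' positions in the collision frame. If the final overlap stays below
#' `min_overlap`, the optimisation is considered failed and positions
#' fall back to momentum extrapolation (status `"fallback"`).
#'
#' @param priors list, one element per participant: list with `mask`
#'   (logical window), `offset` (window origin, px), `centroid` (px) and
#'   `momentum` (px/frame).
#' @param merged the merged detection (list with `mask`, `offset`).
#' @param max_epochs maximum optimisation epochs (default 50).
#' @param min_overlap IoU floor below which the fallback is used.
#' @return list with `positions` (matrix, one row per participant),
#'   `translations`, `iou` and `status` ("resolved" or "fallback").
#' @export
resolve_collision <- function(priors, merged, max_epochs = 50,
                              min_overlap = 0.3) {
  np <- length(priors)
  stopifnot(np >= 1)
  pad <- 8L
  org <- c(merged$offset[1] - pad, merged$offset[2] - pad)
  cn <- c(nrow(merged$mask) + 2L * pad, ncol(merged$mask) + 2L * pad)
  target <- paint_mask(matrix(FALSE, cn[1], cn[2]), merged$mask,
                       c(pad, pad))
  tsum <- sum(target)

  # fractional init matters: slow crawlers move well under a pixel per
  # frame, and rounding the momentum away would erase the motion prior
  # that carries identities through deep overlap
  init <- lapply(priors, function(p) p$momentum)
  trans <- init
  # a tiny pull toward the momentum-initialised translation breaks the
  # plateau degeneracy of fully overlapped, similarly shaped masks
  # without competing with real IoU gradients
  score <- function(trs) {
    u <- matrix(FALSE, cn[1], cn[2])
    dev <- 0
    for (k in seq_len(np)) {
      off <- as.integer(round(priors[[k]]$offset + trs[[k]] - org))
      u <- paint_mask(u, priors[[k]]$mask, off)
      dev <- dev + sqrt(sum((trs[[k]] - init[[k]])^2))
    }
    inter <- sum(u & target)
    inter / (sum(u) + tsum - inter) - 3e-3 * dev
  }
  best <- score(trans)
  moves <- as.matrix(expand.grid(dx = -2:2, dy = -2:2))
  moves <- moves[!(moves[, 1] == 0 & moves[, 2] == 0), , drop = FALSE]
  for (epoch in seq_len(max_epochs)) {
    improved <- FALSE
    for (k in seq_len(np)) {
      for (m in seq_len(nrow(moves))) {
        cand <- trans
        cand[[k]] <- cand[[k]] + moves[m, ]
        s <- score(cand)
        if (s > best + 1e-12) {
          best <- s; trans <- cand; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  pos <- t(vapply(seq_len(np), function(k)
    priors[[k]]$centroid + trans[[k]], numeric(2)))
  status <- "resolved"
  if (best < min_overlap) {
    pos <- t(vapply(seq_len(np), function(k)
      priors[[k]]$centroid + priors[[k]]$momentum, numeric(2)))
    status <- "fallback"
  }
  list(positions = pos, translations = trans, iou = best, status = status)
}
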