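# Shared fixtures: parametric contours and small simulation setups.

# closed ellipse contour (CCW), n vertices, centre (cx, cy)
ellipse_contour <- function(a = 10, b = 3, cx = 20, cy = 20, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th), cy + b * sin(th))
}

# L-shaped tube contour: two straight arms of length `arm` and width
# `w` meeting at a right angle at (0, 0), arms along +x and +y, with
# pointed tips at (arm + w/2, 0) and (0, arm + w/2) so the body ends are
# true contour vertices
l_tube_contour <- function(arm = 12, w = 3, step = 0.25) {
  h <- w / 2
  xs <- seq(h, arm, by = step)
  ys <- seq(h, arm, by = step)
  out <- seq(-h, arm, by = step)
  pts <- rbind(
    c(arm + h, 0),
    cbind(rev(xs), h),          # (arm, h) -> (h, h): inner, +x arm
    cbind(h, ys),               # (h, h) -> (h, arm): inner, +y arm
    c(0, arm + h),              # pointed tip of the +y arm
    cbind(-h, rev(out)),        # (-h, arm) -> (-h, -h): outer wall
    cbind(out, -h))             # (-h, -h) -> (arm, -h): outer wall
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts[keep, ]
}

# straight horizontal tube with rounded ends (mirror-symmetric about y = cy)
straight_tube_contour <- function(len = 12, w = 3, cx = 20, cy = 20,
                                  step = 0.2) {
  h <- w / 2
  xs <- seq(-len / 2, len / 2, by = step)
  thr <- seq(-pi / 2, pi / 2, length.out = 15)
  thl <- seq(pi / 2, 3 * pi / 2, length.out = 15)
  pts <- rbind(cbind(xs, -h),
               cbind(len / 2 + h * cos(thr), h * sin(thr)),
               cbind(rev(xs), h),
               cbind(-len / 2 + h * cos(thl), h * sin(thl)))
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts <- pts[keep, ]
  cbind(pts[, 1] + cx, pts[, 2] + cy)
}

# small clean simulation (no collisions/occlusions/noise) for tracker
# tests
clean_sim_config <- function(n_animals = 3, duration = 40,
                             arena_side = 60, seed = 1, ...) {
  args <- list(...)
  defaults <- list(collision_rate = 0, occlusion_rate = 0, noise_sd = 0,
                   background_drift = 0)
  for (k in names(defaults)) {
    if (is.null(args[[k]])) args[[k]] <- defaults[[k]]
  }
  do.call(sim_config, c(list(n_animals = n_animals, duration = duration,
                             arena_side = arena_side, rng_seed = seed),
                        args))
}

# truth frames for one animal as a track-like data.frame (the interface
# the behaviour/feature modules consume)
truth_as_track <- function(truth, id = 1) {
  tf <- truth$frames[truth$frames$id == id, ]
  tf$interpolated <- FALSE
  tf
}

# synthetic labelled bar crops for the posture network
bar_crops <- function(n, size = 32, seed = 1) {
  set.seed(seed)
  crops <- vector("list", n); keys <- vector("list", n)
  for (i in seq_len(n)) {
    m <- matrix(0, size, size)
    cx <- sample(10:(size - 10), 1); cy <- sample(10:(size - 10), 1)
    ang <- runif(1, 0, 2 * pi)
    hx <- cx + 6 * cos(ang); hy <- cy + 6 * sin(ang)
    tx <- cx - 6 * cos(ang); ty <- cy - 6 * sin(ang)
    for (u in seq(0, 1, by = 0.04)) {
      px <- round(tx + u * (hx - tx)); py <- round(ty + u * (hy - ty))
      if (px >= 1 && px <= size && py >= 1 && py <= size) m[px, py] <- 200
    }
    crops[[i]] <- m
    keys[[i]] <- list(head = c(hx, hy), tail = c(tx, ty))
  }
  list(crops = crops, keys = keys)
}
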