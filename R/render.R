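# Rendering of synthetic larvae into grayscale frames, and frame sources.
#
# Frames are numeric matrices with dim = c(nx, ny): the first index is x
# (rightward), the second y (downward), matching EBImage's convention.
# Values are integers on a 0-255 scale (stored as doubles) so that the
# in-memory frames and an 8-bit lossless image stack round-trip exactly.

#' Create a frame source
#'
#' A frame source is the lazy-video abstraction used throughout the
#' tracker: a list with `n_frames`, `dim`, `frame_rate` and a `get(t)`
#' function returning frame `t` as a matrix. Random access must be
#' deterministic: `get(t)` returns the same matrix regardless of access
#' order.
#'
#' @param get function(t) returning frame t.
#' @param n_frames number of frames.
#' @param dim frame dimensions c(nx, ny).
#' @param frame_rate frames per second.
#' @return an object of class `frame_source`.
#' @export
frame_source <- function(get, n_frames, dim, frame_rate) {
  structure(list(get = get, n_frames = as.integer(n_frames),
                 dim = as.integer(dim), frame_rate = frame_rate),
            class = "frame_source")
}

#' Wrap an in-memory array as a frame source
#'
#' @param arr numeric array with dim c(nx, ny, n_frames).
#' @param frame_rate frames per second.
#' @return a [frame_source()].
#' @export
as_frame_source <- function(arr, frame_rate = 10) {
  stopifnot(length(dim(arr)) == 3)
  frame_source(function(t) arr[, , t], dim(arr)[3], dim(arr)[1:2],
               frame_rate)
}

# Soft-edged bent-larva painter. Body is a two-segment polyline
# tail -> centre -> head with the configured bend angle between segments;
# width tapers toward both ends with a mild head-side boost so the two
# ends are distinguishable. Returns the patch (index ranges + values) so
# the caller can apply it without copying the whole frame.
larva_patch <- function(nx, ny, x_mm, y_mm, heading, bend_deg, cfg) {
  s <- cfg$px_per_mm
  hl <- cfg$larva_length / 2
  br <- deg2rad(bend_deg)
  hx <- x_mm + hl * cos(heading + br / 2)
  hy <- y_mm + hl * sin(heading + br / 2)
  tx <- x_mm - hl * cos(heading - br / 2)
  ty <- y_mm - hl * sin(heading - br / 2)

  p <- mm_to_px(c(tx, x_mm, hx), c(ty, y_mm, hy), s, cfg$arena_side)
  pad <- cfg$larva_width / 2 * s + 2
  i0 <- max(1L, floor(min(p[, 1]) - pad)); i1 <- min(nx, ceiling(max(p[, 1]) + pad))
  j0 <- max(1L, floor(min(p[, 2]) - pad)); j1 <- min(ny, ceiling(max(p[, 2]) + pad))
  if (i0 > i1 || j0 > j1) return(NULL)
  ii <- i0:i1; jj <- j0:j1
  px <- rep(ii - 0.5, times = length(jj))
  py <- rep(jj - 0.5, each = length(ii))

  d1 <- point_segment_dist(px, py, p[1, 1], p[1, 2], p[2, 1], p[2, 2])
  d2 <- point_segment_dist(px, py, p[2, 1], p[2, 2], p[3, 1], p[3, 2])
  use2 <- d2$dist < d1$dist
  d <- d1$dist; d[use2] <- d2$dist[use2]
  u <- d1$t / 2; u[use2] <- 0.5 + d2$t[use2] / 2  # 0 = tail, 1 = head tip

  # width profile (mm -> px): rounded taper, slightly fatter head half
  hw <- cfg$larva_width / 2 * (0.35 + 0.65 * sin(pi * u)^0.7) *
    (1 + 0.15 * u) * s
  val <- cfg$intensity * pmin(1, pmax(0, hw - d + 0.5))
  list(ii = ii, jj = jj, val = matrix(val, nrow = length(ii)))
}

#' Render a ground-truth simulation as a video
#'
#' Renders each visible larva as an elongated bright blob (about 30 px at
#' the default scale) with head/tail asymmetry on a dark background. The
#' background drifts by `background_drift` intensity units per frame along
#' a fixed smooth spatial pattern; additive Gaussian noise of `noise_sd`
#' is applied per pixel; frames are quantised to integer 0-255. During an
#' occlusion event a dark disc (the robot arm) covers the pick-up
#' position and the animal is not drawn.
#'
#' Frames are generated lazily and deterministically: the per-frame noise
#' stream is seeded from `rng_seed` and the frame index, so `get(t)` is
#' reproducible under random access.
#'
#' @param truth a `larva_truth` from [simulate_trajectories()].
#' @param config the [sim_config()] used (defaults to `truth$config`).
#' @return a [frame_source()].
#' @export
render_video <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "larva_truth"))
  cfg <- config
  if (cfg$larva_length * cfg$larva_width * cfg$px_per_mm^2 < 3) {
    stop("rendered animal would be below 3 px; increase px_per_mm",
         call. = FALSE)
  }
  npx <- as.integer(round(cfg$arena_side * cfg$px_per_mm))
  n_frames <- max(truth$frames$frame)

  # fixed smooth drift pattern in [0, 1]
  set.seed(cfg$rng_seed + 7777L)
  ph <- runif(4, 0, 2 * pi)
  gx <- seq(0, 2 * pi, length.out = npx)
  pat <- outer(sin(gx + ph[1]) + 0.6 * sin(2 * gx + ph[2]),
               cos(gx + ph[3]) + 0.6 * sin(2 * gx + ph[4]))
  pat <- (pat - min(pat)) / (max(pat) - min(pat))

  fr_by_frame <- split(truth$frames, truth$frames$frame)
  ev <- truth$events
  occl <- if (nrow(ev)) ev[ev$type == "relocation", , drop = FALSE] else ev

  get <- function(t) {
    drift <- min(cfg$background_drift * (t - 1), 60)
    f <- cfg$background_level + drift * pat
    rows <- fr_by_frame[[t]]
    for (k in seq_len(nrow(rows))) {
      if (!rows$visible[k]) next
      pk <- larva_patch(npx, npx, rows$x[k], rows$y[k], rows$heading[k],
                        rows$bend[k], cfg)
      if (!is.null(pk)) {
        f[pk$ii, pk$jj] <- pmax(f[pk$ii, pk$jj], pk$val)
      }
    }
    if (nrow(occl)) {
      act <- occl[occl$start_frame <= t & occl$end_frame >= t, ,
                  drop = FALSE]
      for (k in seq_len(nrow(act))) {
        c_px <- mm_to_px(act$x_before[k], act$y_before[k],
                         cfg$px_per_mm, cfg$arena_side)
        r <- 6 * cfg$px_per_mm
        i0 <- max(1L, floor(c_px[1] - r)); i1 <- min(npx, ceiling(c_px[1] + r))
        j0 <- max(1L, floor(c_px[2] - r)); j1 <- min(npx, ceiling(c_px[2] + r))
        if (i0 <= i1 && j0 <= j1) {
          ii <- i0:i1; jj <- j0:j1
          dd <- outer((ii - 0.5 - c_px[1])^2, (jj - 0.5 - c_px[2])^2, "+")
          blk <- f[ii, jj]; blk[dd <= r^2] <- 2
          f[ii, jj] <- blk
        }
      }
    }
    if (cfg$noise_sd > 0) {
      set.seed(((cfg$rng_seed %% 10000L) * 100003L + t) %% 2147483647L)
      f <- f + rnorm(npx * npx, 0, cfg$noise_sd)
      f <- pmin(pmax(f, 0), 255)
    }
    round(f)
  }
  frame_source(get, n_frames, c(npx, npx), cfg$frame_rate)
}

#' Write a frame source as a lossless PNG image stack
#'
#' One 8-bit grayscale PNG per frame, named `frame_000001.png` etc. The
#' stack round-trips bit-exactly through [read_frames()].
#'
#' @param src a [frame_source()].
#' @param dir output directory (created if needed).
#' @param frames optional subset of frame indices.
#' @return invisibly, the vector of file paths written.
#' @export
write_frames <- function(src, dir, frames = seq_len(src$n_frames)) {
  stopifnot(inherits(src, "frame_source"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    f <- src$get(t)
    paths[k] <- file.path(dir, sprintf("frame_%06d.png", t))
    # frame is [x, y]; PNG wants [row = y, col = x]
    png::writePNG(t(f) / 255, paths[k])
  }
  invisible(paths)
}

#' Read a PNG image stack as a frame source
#'
#' @param dir directory of grayscale PNG frames (sorted by name).
#' @param frame_rate frames per second of the stack.
#' @return a [frame_source()].
#' @export
read_frames <- function(dir, frame_rate = 10) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", dir,
                               call. = FALSE)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- first[, , 1]
  get <- function(t) {
    m <- png::readPNG(files[t])
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(t(m) * 255)
  }
  frame_source(get, length(files), rev(dim(first)), frame_rate)
}
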