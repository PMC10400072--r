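# Trajectory-level behavioural features: speed, turn rate, curvature,
# turn handedness, navigation index, trajectory stitching and peri-event
# averaging.

#' Crawl speed from a track
#'
#' Central-difference speed: the displacement across a window of
#' `window` seconds centred on each frame, divided by the window
#' duration. Frames whose window anchors are interpolated (or missing)
#' give NA.
#'
#' @param track data.frame with `frame`, `x`, `y` in mm (single animal),
#'   optionally `interpolated`.
#' @param window smoothing window in seconds (>= 2 frames).
#' @param frame_rate frames per second.
#' @return numeric vector of speeds (mm/s), one per row of `track`.
#' @export
compute_speed <- function(track, window = 1, frame_rate = 10) {
  k <- round(window * frame_rate / 2)
  if (window * frame_rate < 2) stop("window must span at least 2 frames",
                                    call. = FALSE)
  k <- max(1, k)
  track <- track[order(track$frame), ]
  n <- nrow(track)
  x <- track$x; y <- track$y
  interp <- if ("interpolated" %in% names(track)) track$interpolated
            else rep(FALSE, n)
  i0 <- pmax(1, seq_len(n) - k)
  i1 <- pmin(n, seq_len(n) + k)
  dt <- (track$frame[i1] - track$frame[i0]) / frame_rate
  sp <- sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2) / dt
  sp[dt <= 0] <- NA
  sp[interp[i0] | interp[i1]] <- NA
  sp
}

#' Turn rate as a sliding-window series
#'
#' @param events turn-event data.frame with `onset_s` (e.g. from
#'   [classify_behavior()]).
#' @param times evaluation time points (s).
#' @param window sliding window length (s), centred.
#' @return turns/min at each time point.
#' @export
compute_turn_rate <- function(events, times, window = 60) {
  vapply(times, function(t0) {
    n <- sum(events$onset_s >= t0 - window / 2 &
             events$onset_s < t0 + window / 2)
    n / window * 60
  }, numeric(1))
}

#' Discrete path curvature
#'
#' The path is resampled at equal arc-length steps and curvature is the
#' wrapped heading change per arc length, signed (positive = bending
#' left/counter-clockwise, matching the turn-direction convention).
#'
#' @param path two-column matrix or data.frame of positions (mm).
#' @param arc_step resampling step (mm).
#' @return data.frame with `s` (arc position, mm) and `curvature` (1/mm).
#' @export
compute_curvature <- function(path, arc_step = 1) {
  path <- as.matrix(path[, 1:2])
  keep <- c(TRUE, rowSums(abs(diff(path))) > 1e-12)  # drop zero steps
  path <- path[keep, , drop = FALSE]
  s <- arc_length(path)
  total <- s[length(s)]
  if (total < 3 * arc_step) stop("path shorter than 3 arc steps",
                                 call. = FALSE)
  m <- floor(total / arc_step) + 1
  rs <- resample_polyline(path, m)
  hd <- atan2(diff(rs[, 2]), diff(rs[, 1]))
  dh <- wrap_angle(diff(hd))
  data.frame(s = arc_step * seq_along(dh), curvature = dh / arc_step)
}

#' Turn handedness statistics
#'
#' `handedness = (N_left - N_right) / N_total`, where +1.0 means all
#' left turns and -1.0 all right turns. Turns with ambiguous direction
#' are excluded from the counts and reported separately.
#'
#' @param events turn-event data.frame with a `direction` column
#'   ("left"/"right", NA = ambiguous) or a signed `size_deg` column.
#' @return object of class `turn_statistics`: list with `n_left`,
#'   `n_right`, `n_total`, `n_ambiguous` and `handedness` (NA when no
#'   countable turns).
#' @export
turn_handedness <- function(events) {
  dir <- if ("direction" %in% names(events)) events$direction
         else ifelse(events$size_deg > 0, "left", "right")
  n_left <- sum(dir == "left", na.rm = TRUE)
  n_right <- sum(dir == "right", na.rm = TRUE)
  n_total <- n_left + n_right
  structure(list(n_left = n_left, n_right = n_right, n_total = n_total,
                 n_ambiguous = sum(is.na(dir)),
                 handedness = if (n_total > 0)
                   (n_left - n_right) / n_total else NA_real_),
            class = "turn_statistics")
}

#' Navigation index
#'
#' The dimensionless index `<v_x>/<v>`: the mean velocity component
#' along the gradient axis divided by the mean speed (mean of norms, so
#' the index lies in [-1, 1]; +1 = crawling straight up-gradient, -1 =
#' straight down-gradient). Frames flagged interpolated or in collision
#' are excluded from the averages. Windows without net motion are
#' undefined and flagged.
#'
#' @param track single-animal data.frame with `frame`, `time`, `x`, `y`
#'   (mm), optionally `interpolated`, `collision`.
#' @param window optional window length (s) for a windowed series; NULL
#'   gives only the whole-track index.
#' @param axis unit vector of the gradient direction (default +x).
#' @param frame_rate frames per second.
#' @return object of class `navigation_index`: list with `overall`,
#'   `n_frames`, and (with `window`) `series` (data.frame `t0`, `t1`,
#'   `index`, `defined`).
#' @export
navigation_index <- function(track, window = NULL, axis = c(1, 0),
                             frame_rate = 10) {
  axis <- axis / sqrt(sum(axis^2))
  track <- track[order(track$frame), ]
  ex <- rep(FALSE, nrow(track))
  if ("interpolated" %in% names(track)) ex <- ex | track$interpolated
  if ("collision" %in% names(track)) ex <- ex | track$collision
  dx <- diff(track$x); dy <- diff(track$y)
  dt <- diff(track$frame) / frame_rate
  ok <- dt > 0 & !ex[-1] & !ex[-length(ex)]
  vx <- (dx * axis[1] + dy * axis[2]) / dt
  vn <- sqrt(dx^2 + dy^2) / dt
  idx_of <- function(sel) {
    sel <- sel & ok
    if (!any(sel) || mean(vn[sel]) == 0) return(NA_real_)
    mean(vx[sel]) / mean(vn[sel])
  }
  overall <- idx_of(rep(TRUE, length(vx)))
  out <- list(overall = overall, n_frames = sum(ok), axis = axis)
  if (!is.null(window)) {
    tmid <- (track$time[-1] + track$time[-nrow(track)]) / 2
    t0s <- seq(min(track$time), max(track$time), by = window)
    series <- do.call(rbind, lapply(t0s, function(t0) {
      sel <- tmid >= t0 & tmid < t0 + window
      v <- idx_of(sel)
      data.frame(t0 = t0, t1 = t0 + window, index = v,
                 defined = !is.na(v))
    }))
    out$series <- series
  }
  structure(out, class = "navigation_index")
}

#' Stitch a trajectory across relocation events
#'
#' Each segment after a relocation (robot pick-up/drop-off) is translated
#' — never rotated, so headings are preserved and "up" stays toward the
#' same arena edge — so that its first point coincides with the previous
#' segment's last point, producing one continuous path.
#'
#' @param track single-animal data.frame with `frame`, `x`, `y` (mm).
#' @param events event data.frame with `type == "relocation"` rows and
#'   `start_frame`, `end_frame` delimiting each gap (e.g. from
#'   [track_video()] or a `larva_truth`).
#' @return object of class `stitched_trajectory`: list with `path`
#'   (data.frame `frame`, `x`, `y`, `segment`), `boundaries` (frame of
#'   each segment start), and `length_m` (cumulative path length in
#'   metres).
#' @export
stitch_trajectory <- function(track, events) {
  track <- track[order(track$frame), ]
  reloc <- events[events$type == "relocation", , drop = FALSE]
  # segment label per row: increments after each relocation gap
  seg <- rep(1L, nrow(track))
  if (nrow(reloc) > 0) {
    for (k in seq_len(nrow(reloc))) {
      seg[track$frame >= reloc$end_frame[k]] <-
        seg[track$frame >= reloc$end_frame[k]] + 1L
    }
  }
  x <- track$x; y <- track$y
  for (s in setdiff(unique(seg), 1L)) {
    i <- which(seg == s)[1]
    prev <- max(which(seg < s))
    x[seg >= s] <- x[seg >= s] - (x[i] - x[prev])
    y[seg >= s] <- y[seg >= s] - (y[i] - y[prev])
  }
  path <- data.frame(frame = track$frame, x = x, y = y, segment = seg)
  len <- sum(sqrt(diff(x)^2 + diff(y)^2)) / 1000
  structure(list(path = path,
                 boundaries = track$frame[!duplicated(seg)],
                 length_m = len),
            class = "stitched_trajectory")
}

#' Event-aligned average of a series
#'
#' Aligns a regularly sampled series on event times and averages across
#' events, with per-timepoint SD. Events without complete flanking data
#' are excluded.
#'
#' @param times sample times (s), uniformly spaced.
#' @param values series values.
#' @param event_times event times (s).
#' @param before,after flank lengths (s).
#' @return object of class `perievent_average`: list with `lag` (s),
#'   `mean`, `sd`, `n_events`.
#' @export
perievent_average <- function(times, values, event_times, before = 300,
                              after = 300) {
  dt <- median(diff(times))
  nb <- round(before / dt); na_ <- round(after / dt)
  lag <- seq(-nb, na_) * dt
  rows <- list()
  for (et in event_times) {
    i <- which.min(abs(times - et))
    if (i - nb < 1 || i + na_ > length(values)) next
    rows[[length(rows) + 1]] <- values[(i - nb):(i + na_)]
  }
  if (length(rows) == 0) stop("no events with complete flanking data",
                              call. = FALSE)
  m <- do.call(rbind, rows)
  structure(list(lag = lag, mean = colMeans(m, na.rm = TRUE),
                 sd = apply(m, 2, sd, na.rm = TRUE),
                 n_events = nrow(m)),
            class = "perievent_average")
}
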