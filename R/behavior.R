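# Run/turn behavioural segmentation: deterministic heuristic classifier,
# switching-cost decoding and turn-event extraction.

#' Decode a state path under a switching cost
#'
#' Two(+)-state dynamic program over per-frame state probabilities: the
#' path minimises the summed negative log-probabilities plus `cost` for
#' every state transition. With `cost = 0` this is the per-frame argmax;
#' as `cost` grows the path collapses to a single state. Increasing the
#' cost never increases the number of transitions.
#'
#' @param probs matrix [frames, states] of per-frame probabilities.
#' @param cost non-negative per-transition penalty (natural-log units).
#' @return integer vector of state indices per frame.
#' @export
apply_switching_cost <- function(probs, cost) {
  stopifnot(is.matrix(probs), cost >= 0)
  T <- nrow(probs); k <- ncol(probs)
  nl <- -log(pmax(probs, 1e-12))
  dp <- matrix(Inf, T, k)
  bk <- matrix(0L, T, k)
  dp[1, ] <- nl[1, ]
  for (t in 2:T) {
    for (s in seq_len(k)) {
      cand <- dp[t - 1, ] + cost * (seq_len(k) != s)
      j <- which.min(cand)
      dp[t, s] <- cand[j] + nl[t, s]
      bk[t, s] <- j
    }
  }
  path <- integer(T)
  path[T] <- which.min(dp[T, ])
  for (t in (T - 1):1) path[t] <- bk[t + 1, path[t + 1]]
  path
}

# merge state blocks shorter than min_block into their neighbours,
# shortest first; implements the switching cost deterministically
merge_short_blocks <- function(states, min_block) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_block)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    # absorb into the longer neighbour (flip the block's state)
    r$values[i] <- if (i == 1) r$values[2]
      else if (i == length(r$values)) r$values[i - 1]
      else if (r$lengths[i - 1] >= r$lengths[i + 1]) r$values[i - 1]
      else r$values[i + 1]
    states <- inverse.rle(r)
  }
  states
}

# heading (rad, mm coordinates) from displacement over +/- k frames
local_heading <- function(x, y, idx, k = 5) {
  n <- length(x)
  i0 <- max(1, idx - k); i1 <- min(n, idx + k)
  atan2(y[i1] - y[i0], x[i1] - x[i0])
}

#' Heuristic run/turn classification
#'
#' Deterministic segmentation of a single-animal track: a frame is a turn
#' candidate when the body bend exceeds `bend_threshold` while the crawl
#' speed falls below `speed_threshold`; runs are everything else. Blocks
#' shorter than `min_block` are merged into their neighbours, which plays
#' the role of an explicit cost for switching behavioural states.
#' Interpolated frames are never turn candidates. Each maximal turn block
#' becomes a turn event whose signed size is the wrapped difference
#' between the local run heading after and before the block (positive =
#' left/counter-clockwise in mm coordinates).
#'
#' @param track data.frame for one animal with columns `frame`, `time`,
#'   `x`, `y` (mm), `bend` (deg) and optionally `interpolated`.
#' @param frame_rate frames per second.
#' @param bend_threshold degrees.
#' @param speed_threshold mm/s; default 40% of the animal's median
#'   positive speed.
#' @param min_block frames; blocks shorter than this are merged away.
#' @return an object of class `behavior_sequence`: list with `states`
#'   (character per frame), `probs` (matrix, rows sum to 1), `events`
#'   (data.frame `onset_frame`, `offset_frame`, `onset_s`, `offset_s`,
#'   `size_deg`, `direction`), and `frames`.
#' @export
classify_behavior <- function(track, frame_rate, bend_threshold = 20,
                              speed_threshold = NULL, min_block = 3) {
  stopifnot(all(c("frame", "x", "y", "bend") %in% names(track)))
  if (length(unique(track$id)) > 1) {
    stop("classify_behavior expects a single animal; split by id first",
         call. = FALSE)
  }
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < min_block) stop("series shorter than min_block", call. = FALSE)
  sp <- compute_speed(track, window = 0.5, frame_rate = frame_rate)
  if (is.null(speed_threshold)) {
    pos <- sp[is.finite(sp) & sp > 0]
    speed_threshold <- 0.4 * if (length(pos)) median(pos) else Inf
  }
  interp <- if ("interpolated" %in% names(track)) track$interpolated
            else rep(FALSE, n)
  bend <- track$bend
  bend[is.na(bend)] <- 0
  turn_raw <- abs(bend) > bend_threshold &
    (!is.finite(sp) | sp < speed_threshold) & !interp
  states <- merge_short_blocks(ifelse(turn_raw, "turn", "run"), min_block)

  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- list()
  for (i in which(r$values == "turn")) {
    pre <- local_heading(track$x, track$y, max(1, starts[i] - 3), k = 5)
    post <- local_heading(track$x, track$y, min(n, ends[i] + 3), k = 5)
    size <- wrap_deg(rad2deg(post - pre))
    # events at the series edge lack a flanking run heading; a zero net
    # heading change has no direction either
    ambiguous <- starts[i] <= 5 || ends[i] >= n - 5 || size == 0
    ev[[length(ev) + 1]] <- data.frame(
      onset_frame = track$frame[starts[i]],
      offset_frame = track$frame[ends[i]],
      onset_s = (track$frame[starts[i]] - 1) / frame_rate,
      offset_s = (track$frame[ends[i]] - 1) / frame_rate,
      size_deg = if (ambiguous) NA_real_ else size,
      direction = if (ambiguous) NA_character_
                  else if (size > 0) "left" else "right")
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset_frame = integer(0), offset_frame = integer(0),
               onset_s = numeric(0), offset_s = numeric(0),
               size_deg = numeric(0), direction = character(0))
  probs <- cbind(run = as.numeric(states == "run"),
                 turn = as.numeric(states == "turn"))
  structure(list(states = states, probs = probs, events = events,
                 frames = track$frame,
                 params = list(bend_threshold = bend_threshold,
                               speed_threshold = speed_threshold,
                               min_block = min_block)),
            class = "behavior_sequence")
}
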