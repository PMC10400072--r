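# High-level tracker: video in, identity-preserved track table out.

#' Tracker configuration
#'
#' @param alpha background feedforward coefficient (see
#'   [background_model()]).
#' @param threshold intensity offset for foreground segmentation.
#' @param min_area,max_area single-animal pixel-area gate.
#' @param merged_area_factor detections up to
#'   `max_area * merged_area_factor` are kept as merged-contour
#'   (collision) candidates.
#' @param linking a [linking_config()].
#' @param collision_max_epochs epoch cap for [resolve_collision()].
#' @param n_animals cap on simultaneously open tracks (Inf = uncapped).
#'   When the cap is reached, an unmatched detection is force-matched to
#'   the best missing track, which is how relocated (picked-up) animals
#'   are re-acquired.
#' @param px_per_mm imaging scale used to convert output to mm.
#' @param relocation_jump gap-bridging jumps longer than this (mm) are
#'   logged as relocation events and not interpolated.
#' @param bg_init `"first"` (first frame) or `"median"` (pixelwise median
#'   of the first `bg_init_n` frames).
#' @param bg_init_n frames used when `bg_init = "median"`.
#' @param posture compute head/tail/spine posture per frame (slower).
#' @param n_spine_points spine resolution when `posture = TRUE` (odd).
#' @return an object of class `track_config`.
#' @export
track_config <- function(alpha = 0.01, threshold = 40, min_area = 10,
                         max_area = 45, merged_area_factor = 4,
                         linking = linking_config(),
                         collision_max_epochs = 50, n_animals = Inf,
                         px_per_mm = 4, relocation_jump = 20,
                         bg_init = c("first", "median"), bg_init_n = 10,
                         posture = FALSE, n_spine_points = 11) {
  stopifnot(alpha >= 0, alpha <= 1, threshold >= 0,
            min_area > 0, min_area < max_area, merged_area_factor >= 1)
  structure(list(alpha = alpha, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 merged_area_factor = merged_area_factor,
                 linking = linking,
                 collision_max_epochs = collision_max_epochs,
                 n_animals = n_animals, px_per_mm = px_per_mm,
                 relocation_jump = relocation_jump,
                 bg_init = match.arg(bg_init),
                 bg_init_n = as.integer(bg_init_n),
                 posture = posture,
                 n_spine_points = as.integer(n_spine_points)),
            class = "track_config")
}

# momentum from a position history matrix (rows = recent frames, px):
# mean displacement per frame over up to `window` most recent steps
momentum_from_history <- function(hist, window) {
  n <- nrow(hist)
  if (n < 2) return(c(0, 0))
  k <- min(window, n - 1)
  (hist[n, ] - hist[n - k, ]) / k
}

#' Track larvae through a video
#'
#' Runs the full position-tracking stage: IIR background subtraction,
#' size-gated contour detection, greedy identity linking, gap
#' interpolation, relocation handling and collision resolution. Optionally
#' attaches posture (head/tail keypoints, midspine, body bend) from the
#' detection contours.
#'
#' @param src a [frame_source()].
#' @param cfg a [track_config()].
#' @param verbose print per-stage progress every 500 frames.
#' @return an object of class `larva_tracks`: list with
#'   \describe{
#'     \item{tracks}{data.frame: `frame`, `time`, `id`, `x_px`, `y_px`,
#'       `x`, `y` (mm), `area`, `interpolated`, `collision` and, with
#'       `posture = TRUE`, `head_x`, `head_y`, `tail_x`, `tail_y` (mm),
#'       `mid_x`, `mid_y` (midspine, mm), `bend` (deg) and
#'       `posture_conf`.}
#'     \item{events}{relocations and collision spans.}
#'     \item{det_counts}{detections per frame (within the single-animal
#'       gate).}
#'     \item{config}{the tracker configuration.}
#'   }
#' @export
track_video <- function(src, cfg = track_config(), verbose = FALSE) {
  stopifnot(inherits(src, "frame_source"), inherits(cfg, "track_config"))
  lk <- cfg$linking
  n_frames <- src$n_frames
  arena_mm <- src$dim[2] / cfg$px_per_mm
  fr <- src$frame_rate

  # background initialisation
  if (cfg$bg_init == "median") {
    nb <- min(cfg$bg_init_n, n_frames)
    stack <- vapply(seq_len(nb), function(t) src$get(t),
                    matrix(0, src$dim[1], src$dim[2]))
    init <- apply(stack, c(1, 2), median)
  } else {
    init <- src$get(1)
  }
  bm <- background_model(init, cfg$alpha)

  tracks <- list()          # mutable per-track environments
  next_id <- 1L
  rows <- vector("list", n_frames)
  det_counts <- integer(n_frames)
  events <- list()
  coll_frames <- list()     # per-frame collision participant ids

  new_track <- function(det, t) {
    e <- new.env(parent = emptyenv())
    e$id <- next_id; next_id <<- next_id + 1L
    e$hist <- matrix(det$centroid, 1, 2)
    e$hist_frames <- t
    e$r <- det$centroid; e$p <- c(0, 0); e$a <- det$area
    e$last_seen <- t; e$missing <- 0L; e$closed <- FALSE
    e$in_collision <- FALSE
    e$mask <- det$mask; e$offset <- det$offset; e$contour <- det$contour
    e$posture <- NULL
    e
  }

  as_state <- function(e) track_state(e$id, e$r, e$p, e$a, e$last_seen)

  observe <- function(e, det, t, collision = FALSE) {
    # back-fill a bridged gap, or log a relocation for large jumps
    if (e$missing > 0L) {
      gap <- (e$last_seen + 1L):(t - 1L)
      jump_mm <- sqrt(sum((det$centroid - e$r)^2)) / cfg$px_per_mm
      if (jump_mm > cfg$relocation_jump) {
        events[[length(events) + 1]] <<- data.frame(
          type = "relocation", id = e$id, id2 = NA_integer_,
          start_frame = e$last_seen, end_frame = t,
          x_before = e$r[1], y_before = e$r[2],
          x_after = det$centroid[1], y_after = det$centroid[2],
          status = "gap")
        e$hist <- matrix(det$centroid, 1, 2)  # momentum restarts
      } else if (length(gap) > 0) {
        fill <- interpolate_gaps(
          data.frame(frame = c(e$last_seen, t),
                     x = c(e$r[1], det$centroid[1]),
                     y = c(e$r[2], det$centroid[2])),
          gap)
        for (gi in seq_len(nrow(fill))) {
          rows[[fill$frame[gi]]] <<- append(
            rows[[fill$frame[gi]]],
            list(list(frame = fill$frame[gi], id = e$id,
                      x = fill$x[gi], y = fill$y[gi], a = e$a,
                      interpolated = TRUE, collision = FALSE,
                      posture = NULL)))
        }
      }
    }
    e$hist <- rbind(e$hist, det$centroid)
    if (nrow(e$hist) > lk$momentum_window + 1L) {
      e$hist <- e$hist[-1, , drop = FALSE]
    }
    e$r <- det$centroid
    e$p <- momentum_from_history(e$hist, lk$momentum_window)
    e$a <- det$area
    e$mask <- det$mask; e$offset <- det$offset; e$contour <- det$contour
    e$last_seen <- t; e$missing <- 0L; e$in_collision <- collision
    if (cfg$posture && !collision && !is.null(det$contour) &&
        nrow(det$contour) >= 8) {
      e$posture <- estimate_head_tail(det$contour, e$posture, e$p)
      if (!is.na(e$posture$head[1])) {
        sp <- try(compute_spine(det$contour, e$posture$head,
                                e$posture$tail, cfg$n_spine_points),
                  silent = TRUE)
        if (!inherits(sp, "try-error")) e$posture$spine <- sp
      }
    }
    rows[[t]] <<- append(rows[[t]], list(list(
      frame = t, id = e$id, x = det$centroid[1], y = det$centroid[2],
      a = det$area, interpolated = FALSE, collision = collision,
      posture = if (cfg$posture) e$posture else NULL)))
  }

  for (t in seq_len(n_frames)) {
    f <- src$get(t)
    dets <- detect_frame(f, bm, cfg$threshold, cfg$min_area,
                         cfg$max_area * cfg$merged_area_factor, t,
                         adopt_host_max = cfg$max_area)
    bm <- update_background(bm, f)
    is_big <- vapply(dets, function(d) d$area > cfg$max_area, logical(1))
    normal <- dets[!is_big]; big <- dets[is_big]
    det_counts[t] <- length(normal)

    open <- Filter(function(e) !e$closed, tracks)
    consumed <- rep(FALSE, length(open))

    # --- collisions -----------------------------------------------------
    if (length(big) > 0 && length(open) > 0) {
      states <- lapply(open, as_state)
      evs <- detect_collision(big, states, cfg$max_area)
      handled_big <- rep(FALSE, length(big))
      for (ev in evs) {
        idx <- ev$participants[!consumed[ev$participants]]
        if (length(idx) < 2) next
        priors <- lapply(open[idx], function(e)
          list(mask = e$mask, offset = e$offset, centroid = e$r,
               momentum = e$p))
        res <- resolve_collision(priors, big[[ev$det_idx]],
                                 cfg$collision_max_epochs)
        for (k in seq_along(idx)) {
          e <- open[[idx[k]]]
          fake <- list(centroid = res$positions[k, ], area = e$a,
                       mask = e$mask, offset = e$offset + res$translations[[k]],
                       contour = NULL)
          observe(e, fake, t, collision = TRUE)
        }
        consumed[idx] <- TRUE
        handled_big[ev$det_idx] <- TRUE
        coll_frames[[length(coll_frames) + 1]] <- data.frame(
          frame = t, ids = I(list(ev$ids)), status = res$status)
      }
      # an oversized blob with a single (previously colliding or lone)
      # candidate behaves as an ordinary detection for that track
      if (any(!handled_big)) normal <- c(normal, big[!handled_big])
    }

    # --- greedy linking -------------------------------------------------
    rem_idx <- which(!consumed)
    states <- lapply(open[rem_idx], as_state)
    asg <- assign_identities(normal, states, lk)
    if (nrow(asg$matches) > 0) {
      for (k in seq_len(nrow(asg$matches))) {
        e <- open[[rem_idx[asg$matches$track_idx[k]]]]
        observe(e, normal[[asg$matches$det_idx[k]]], t)
      }
    }

    # --- unmatched tracks: missing / closed -----------------------------
    for (i in asg$unmatched_tracks) {
      e <- open[[rem_idx[i]]]
      e$missing <- e$missing + 1L
      e$in_collision <- FALSE
      if (e$missing > lk$interp_max_gap) e$closed <- TRUE
    }

    # --- unmatched detections: new tracks or forced re-acquisition ------
    un_d <- asg$unmatched_dets
    if (length(un_d) > 0) {
      n_open <- sum(vapply(tracks, function(e) !e$closed, logical(1)))
      for (j in un_d) {
        if (n_open < cfg$n_animals) {
          tracks[[length(tracks) + 1]] <- new_track(normal[[j]], t)
          n_open <- n_open + 1L
        } else {
          missing_tracks <- Filter(function(e) !e$closed && e$missing > 0L,
                                   tracks)
          if (length(missing_tracks) == 0) next  # spurious detection
          losses <- vapply(missing_tracks, function(e)
            link_loss(normal[[j]], as_state(e), lk), numeric(1))
          ids <- vapply(missing_tracks, function(e) e$id, integer(1))
          e <- missing_tracks[[order(losses, ids)[1]]]
          observe(e, normal[[j]], t)
        }
      }
    }

    if (verbose && t %% 500 == 0) {
      message(sprintf("frame %d/%d: %d detections, %d open tracks",
                      t, n_frames, det_counts[t],
                      sum(vapply(tracks, function(e) !e$closed,
                                 logical(1)))))
    }
  }

  # --- assemble output table -------------------------------------------
  flat <- unlist(rows, recursive = FALSE)
  n <- length(flat)
  df <- data.frame(
    frame = vapply(flat, `[[`, integer(1), "frame"),
    id = vapply(flat, `[[`, integer(1), "id"),
    x_px = vapply(flat, `[[`, numeric(1), "x"),
    y_px = vapply(flat, `[[`, numeric(1), "y"),
    area = vapply(flat, function(z) as.numeric(z$a), numeric(1)),
    interpolated = vapply(flat, `[[`, logical(1), "interpolated"),
    collision = vapply(flat, `[[`, logical(1), "collision"))
  df$time <- (df$frame - 1) / fr
  mm <- px_to_mm(df$x_px, df$y_px, cfg$px_per_mm, arena_mm)
  df$x <- mm[, 1]; df$y <- mm[, 2]
  if (cfg$posture) {
    getp <- function(z, what, k) {
      p <- z$posture
      if (is.null(p)) return(NA_real_)
      if (what == "conf") return(p$confidence)
      if (what %in% c("head", "tail")) return(p[[what]][k])
      if (is.null(p$spine)) return(NA_real_)
      if (what == "mid") return(p$spine$midspine[k])
      if (what == "bend") return(p$spine$body_bend)
      NA_real_
    }
    hx <- vapply(flat, getp, numeric(1), "head", 1)
    hy <- vapply(flat, getp, numeric(1), "head", 2)
    tx <- vapply(flat, getp, numeric(1), "tail", 1)
    ty <- vapply(flat, getp, numeric(1), "tail", 2)
    mx <- vapply(flat, getp, numeric(1), "mid", 1)
    my <- vapply(flat, getp, numeric(1), "mid", 2)
    hmm <- px_to_mm(hx, hy, cfg$px_per_mm, arena_mm)
    tmm <- px_to_mm(tx, ty, cfg$px_per_mm, arena_mm)
    mmm <- px_to_mm(mx, my, cfg$px_per_mm, arena_mm)
    df$head_x <- hmm[, 1]; df$head_y <- hmm[, 2]
    df$tail_x <- tmm[, 1]; df$tail_y <- tmm[, 2]
    df$mid_x <- mmm[, 1]; df$mid_y <- mmm[, 2]
    # sign flip: bend is computed in image coordinates (y down); report
    # it in mm coordinates (y up, left = positive)
    df$bend <- -vapply(flat, getp, numeric(1), "bend", 1)
    df$posture_conf <- vapply(flat, getp, numeric(1), "conf", 1)
  }
  df <- df[order(df$id, df$frame),
           c("frame", "time", "id", "x_px", "y_px", "x", "y", "area",
             "interpolated", "collision",
             setdiff(names(df), c("frame", "time", "id", "x_px", "y_px",
                                  "x", "y", "area", "interpolated",
                                  "collision")))]
  rownames(df) <- NULL

  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), id = integer(0), id2 = integer(0),
               start_frame = integer(0), end_frame = integer(0),
               x_before = numeric(0), y_before = numeric(0),
               x_after = numeric(0), y_after = numeric(0),
               status = character(0))
  coll_df <- if (length(coll_frames)) do.call(rbind, coll_frames) else
    data.frame(frame = integer(0), ids = I(list()), status = character(0))

  structure(list(tracks = df, events = ev_df, collisions = coll_df,
                 det_counts = det_counts, config = cfg),
            class = "larva_tracks")
}

#' Match tracked identities to ground-truth identities
#'
#' Builds the track-id to truth-id correspondence from the first frames
#' of each track (nearest true position), then scores per-frame identity
#' agreement: a frame counts as correct for a track when its position
#' lies nearer to its corresponding true animal than to any other.
#'
#' @param tracked a `larva_tracks` object.
#' @param truth a `larva_truth` object.
#' @param max_dist match tolerance in mm.
#' @return list with `mapping` (track id -> truth id), `frame_accuracy`
#'   (fraction of non-interpolated tracked frames with correct identity)
#'   and `per_frame` (data.frame of scored frames).
#' @export
match_tracks_to_truth <- function(tracked, truth, max_dist = 3) {
  tr <- tracked$tracks
  tf <- truth$frames
  ids <- sort(unique(tr$id))
  mapping <- setNames(integer(length(ids)), ids)
  for (k in seq_along(ids)) {
    first <- tr[tr$id == ids[k], ][1, ]
    cand <- tf[tf$frame == first$frame & tf$visible, ]
    d <- sqrt((cand$x - first$x)^2 + (cand$y - first$y)^2)
    mapping[k] <- cand$id[which.min(d)]
  }
  key <- paste(tf$frame, tf$id)
  scored <- tr[!tr$interpolated, ]
  true_id <- mapping[as.character(scored$id)]
  m <- match(paste(scored$frame, true_id), key)
  dx <- scored$x - tf$x[m]; dy <- scored$y - tf$y[m]
  dist_own <- sqrt(dx^2 + dy^2)
  # distance to the nearest *other* true animal in the same frame
  correct <- logical(nrow(scored))
  by_frame <- split(tf[tf$visible, ], tf$frame[tf$visible])
  for (i in seq_len(nrow(scored))) {
    cand <- by_frame[[as.character(scored$frame[i])]]
    others <- cand[cand$id != true_id[i], ]
    d_other <- if (nrow(others)) min(sqrt((others$x - scored$x[i])^2 +
                                          (others$y - scored$y[i])^2))
               else Inf
    correct[i] <- is.finite(dist_own[i]) && dist_own[i] <= max_dist &&
      dist_own[i] < d_other
  }
  list(mapping = mapping,
       frame_accuracy = mean(correct),
       per_frame = data.frame(frame = scored$frame, id = scored$id,
                              true_id = true_id, dist = dist_own,
                              correct = correct))
}
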