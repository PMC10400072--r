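# Dynamic background model (IIR running average) and per-frame detection.

#' Create a dynamic background model
#'
#' The background estimate is an exponentially weighted running average of
#' frames, updated as `B_t = alpha * F_t + (1 - alpha) * B_{t-1}` — an
#' infinite-impulse-response filter that tracks slow changes (condensation,
#' dust, substrate ageing) while washing out the moving animals. `alpha`
#' is the feedforward coefficient; the default 0.01 at 10 Hz gives a
#' background time constant of roughly 10 s.
#'
#' @param init initial background image (matrix). Typically the first
#'   frame; animals bleed into the background initially and wash out with
#'   the filter. Alternatively supply a median of the first N frames.
#' @param alpha feedforward coefficient in [0, 1].
#' @return an object of class `background_model` with fields `B` and
#'   `alpha`.
#' @export
background_model <- function(init, alpha = 0.01) {
  stopifnot(is.matrix(init), alpha >= 0, alpha <= 1)
  structure(list(B = init, alpha = alpha), class = "background_model")
}

#' Update the background with a new frame
#'
#' Pure update: returns a new model with `B <- alpha*F + (1-alpha)*B`;
#' the input model is not modified. Since the update is a convex
#' combination, B stays within the intensity range of the frames.
#'
#' @param model a [background_model()].
#' @param frame matrix of the same shape as `model$B`.
#' @return the updated `background_model`.
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(model$B), dim(frame))) {
    stop("frame shape does not match background", call. = FALSE)
  }
  model$B <- model$alpha * frame + (1 - model$alpha) * model$B
  model
}

#' Subtract the background and threshold
#'
#' Computes the clipped residual `max(F - B, 0)` and returns the binary
#' mask of pixels exceeding `threshold`.
#'
#' @param frame image matrix.
#' @param model a [background_model()].
#' @param threshold non-negative intensity offset.
#' @return logical matrix of foreground pixels.
#' @export
subtract_and_threshold <- function(frame, model, threshold) {
  stopifnot(threshold >= 0)
  # clipping negative residuals to zero cannot change the comparison for
  # threshold >= 0, so the clip is folded into the single pass below
  (frame - model$B) > threshold
}

#' Extract size-gated detections from a binary mask
#'
#' Connected bright components are labelled, holes are filled so that only
#' outermost contours are considered, and components with pixel area
#' outside `[min_area, max_area]` are discarded. Centroids are the mean of
#' the component's pixel centres.
#'
#' @param mask logical matrix (first index x, second y).
#' @param min_area,max_area inclusive pixel-area gate, 0 < min < max.
#' @param frame_index frame number recorded in each detection.
#' @param adopt_host_max fragments are only folded into components no
#'   larger than this (default `max_area`): an oversized merged contour
#'   never swallows a small neighbour, which may be an animal in the act
#'   of separating from a collision.
#' @return list of `larva_detection` objects, each a list with `frame`,
#'   `centroid` (px), `area` (px^2), `bbox` (xmin, xmax, ymin, ymax),
#'   `offset` (bbox origin, px), `mask` (logical window) and `contour`
#'   (n x 2 ordered boundary vertices at pixel-centre coordinates).
#' @export
extract_detections <- function(mask, min_area, max_area,
                               frame_index = NA_integer_,
                               adopt_host_max = max_area) {
  stopifnot(min_area > 0, min_area < max_area)
  if (!any(mask)) return(list())
  filled <- EBImage::fillHull(mask * 1)
  lab <- EBImage::bwlabel(filled)
  # fragment adoption: bwlabel is 4-connected, so the sub-pixel-wide
  # tail of a sharply bent animal can break off along diagonals. A
  # component too small to be an animal (< 2 * min_area) that touches a
  # neighbour across the diagonal gap (found via a dilated relabelling)
  # is folded into that neighbour's component. Full-sized components are
  # never merged this way, so two touching animals still join only on
  # true pixel adjacency.
  areas4 <- tabulate(lab)
  small <- which(areas4 > 0 & areas4 < 2 * min_area)
  if (length(small) > 0 && length(areas4) > 1) {
    labd <- EBImage::bwlabel(EBImage::dilate(filled, matrix(1, 3, 3)))
    for (l in small) {
      pix_l <- which(lab == l)
      g <- labd[pix_l[1]]
      mates <- setdiff(unique(lab[labd == g & lab > 0]), l)
      mates <- mates[areas4[mates] <= adopt_host_max]
      if (length(mates) > 0) {
        host <- mates[which.max(areas4[mates])]
        lab[pix_l] <- host
      }
    }
    # renumber labels consecutively
    ids <- sort(unique(lab[lab > 0]))
    lab <- matrix(match(lab, ids, nomatch = 0L) * (lab > 0),
                  nrow(lab), ncol(lab))
  }
  nlab <- max(lab)
  if (nlab == 0) return(list())
  contours <- EBImage::ocontour(lab)
  # one pass over foreground pixels, then group by label
  fg <- which(lab > 0)
  nx <- nrow(lab)
  pix <- split(fg, lab[fg])
  out <- list()
  for (l in seq_len(nlab)) {
    lin <- pix[[as.character(l)]]
    idx <- cbind((lin - 1L) %% nx + 1L, (lin - 1L) %/% nx + 1L)
    area <- nrow(idx)
    if (area < min_area || area > max_area) next
    # pixel centres are at index - 0.5
    centroid <- c(mean(idx[, 1]) - 0.5, mean(idx[, 2]) - 0.5)
    bbox <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
    win <- matrix(FALSE, bbox[2] - bbox[1] + 1L, bbox[4] - bbox[3] + 1L)
    win[cbind(idx[, 1] - bbox[1] + 1L, idx[, 2] - bbox[3] + 1L)] <- TRUE
    out[[length(out) + 1]] <- structure(
      list(frame = frame_index, centroid = centroid, area = area,
           bbox = bbox, offset = c(bbox[1] - 1L, bbox[3] - 1L),
           # ocontour is 0-based pixel indices; store pixel centres
           mask = win, contour = contours[[l]] + 0.5),
      class = "larva_detection")
  }
  out
}

#' Detect larvae in one frame against a background model
#'
#' Convenience wrapper: subtract, threshold, extract.
#'
#' @inheritParams subtract_and_threshold
#' @inheritParams extract_detections
#' @return list of detections (see [extract_detections()]).
#' @export
detect_frame <- function(frame, model, threshold, min_area, max_area,
                         frame_index = NA_integer_,
                         adopt_host_max = max_area) {
  extract_detections(subtract_and_threshold(frame, model, threshold),
                     min_area, max_area, frame_index,
                     adopt_host_max = adopt_host_max)
}
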