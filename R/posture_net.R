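# Recurrent U-Net heatmap network for head/tail keypoints.
#
# Encoder-decoder with skip connections and convolutional LSTM cells at
# the encoder input, the bottleneck and the decoder output. The output is
# a two-channel per-pixel probability map (head, tail), each channel
# normalised to sum to one. Larvae are sparse clusters of ~30 bright
# pixels, so the temporal recurrence carries posture information between
# frames and penalises head/tail flips.

# one ConvLSTM step; x, h are [H, W, C] nodes, cc the cell state node
conv_lstm_step <- function(x, h, cc, W, b, ch) {
  z <- ag_conv3(ag_cat_channels(x, h), W, b)
  i <- ag_sigmoid(ag_channels(z, 1, ch))
  f <- ag_sigmoid(ag_channels(z, ch + 1, 2 * ch))
  o <- ag_sigmoid(ag_channels(z, 2 * ch + 1, 3 * ch))
  g <- ag_tanh(ag_channels(z, 3 * ch + 1, 4 * ch))
  c_new <- ag_add(ag_mul(f, cc), ag_mul(i, g))
  h_new <- ag_mul(o, ag_tanh(c_new))
  list(h = h_new, c = c_new)
}

#' Build the recurrent U-Net posture network
#'
#' Constructs the encoder-decoder heatmap architecture: `depth` encoder
#' submodules of (3x3 convolution, ReLU, 2x2 max pooling), mirrored by a
#' decoder with nearest-neighbour upsampling in place of pooling, skip
#' connections between corresponding submodules, and convolutional LSTM
#' recurrence at the encoder input, the bottleneck and the decoder
#' output. The final layer emits two channels whose spatial softmax gives
#' per-pixel probability maps of the head and the tail.
#'
#' The implementation is a faithful small-scale architecture with a
#' synthetic-data training loop; the deterministic geometric estimator
#' ([estimate_head_tail()]) remains the default pipeline path.
#'
#' @param input_size crop side in px; must be divisible by `2^depth`.
#' @param base_channels channels of the first encoder submodule.
#' @param depth number of encoder submodules; the decoder always mirrors
#'   it (a mismatched decoder is not constructible).
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `heatmap_network`.
#' @export
build_heatmap_network <- function(input_size = 64, base_channels = 4,
                                  depth = 4, seed = 1) {
  if (depth < 1 || input_size %% (2^depth) != 0) {
    stop("invalid config: input_size must be divisible by 2^depth",
         call. = FALSE)
  }
  set.seed(seed)
  ch <- base_channels * pmin(2^(seq_len(depth) - 1), 4)
  p <- list()
  cin <- 1
  for (k in seq_len(depth)) {
    p[[paste0("We", k)]] <- ag_param(ag_init(9 * cin, ch[k], 9 * cin))
    p[[paste0("be", k)]] <- ag_param(numeric(ch[k]))
    cin <- ch[k]
  }
  cb <- ch[depth]
  p$Wlin <- ag_param(ag_init(9 * 2 * ch[1], 4 * ch[1], 9 * 2 * ch[1]))
  p$blin <- ag_param(numeric(4 * ch[1]))
  p$Wlbn <- ag_param(ag_init(9 * 2 * cb, 4 * cb, 9 * 2 * cb))
  p$blbn <- ag_param(numeric(4 * cb))
  for (k in rev(seq_len(depth))) {
    cskip <- ch[k]
    # decoder stage k consumes the output of stage k+1 (ch[k] channels,
    # since stage k+1 emits ch[(k+1)-1]); the deepest stage consumes the
    # bottleneck
    cup <- if (k == depth) cb else ch[k]
    cout <- if (k == 1) ch[1] else ch[k - 1]
    p[[paste0("Wd", k)]] <- ag_param(ag_init(9 * (cup + cskip), cout,
                                             9 * (cup + cskip)))
    p[[paste0("bd", k)]] <- ag_param(numeric(cout))
  }
  p$Wlout <- ag_param(ag_init(9 * 2 * ch[1], 4 * ch[1], 9 * 2 * ch[1]))
  p$blout <- ag_param(numeric(4 * ch[1]))
  p$Whead <- ag_param(ag_init(9 * ch[1], 2, 9 * ch[1]))
  p$bhead <- ag_param(numeric(2))

  net <- new.env(parent = emptyenv())
  net$params <- p
  net$input_size <- input_size
  net$depth <- depth
  net$channels <- ch
  net$state <- NULL
  class(net) <- "heatmap_network"
  net
}

#' Reset the recurrent state of a posture network
#' @param net a `heatmap_network`.
#' @export
reset_state <- function(net) {
  net$state <- NULL
  invisible(net)
}

zero_state_heatmap <- function(net) {
  n <- net$input_size
  c1 <- net$channels[1]
  cb <- net$channels[net$depth]
  nb <- n / 2^net$depth
  list(h_in = array(0, c(n, n, c1)), c_in = array(0, c(n, n, c1)),
       h_bn = array(0, c(nb, nb, cb)), c_bn = array(0, c(nb, nb, cb)),
       h_out = array(0, c(n, n, c1)), c_out = array(0, c(n, n, c1)))
}

# full forward pass; returns nodes for training and the probability maps
heatmap_forward <- function(net, crop, state = NULL) {
  p <- net$params
  if (is.null(state)) state <- zero_state_heatmap(net)
  x <- ag_const(array(crop, c(dim(crop), 1)))
  skips <- vector("list", net$depth)
  for (k in seq_len(net$depth)) {
    x <- ag_relu(ag_conv3(x, p[[paste0("We", k)]], p[[paste0("be", k)]]))
    if (k == 1) {
      st <- conv_lstm_step(x, ag_const(state$h_in), ag_const(state$c_in),
                           p$Wlin, p$blin, net$channels[1])
      x <- st$h
      new_h_in <- st$h; new_c_in <- st$c
    }
    skips[[k]] <- x
    x <- ag_pool2(x)
  }
  st <- conv_lstm_step(x, ag_const(state$h_bn), ag_const(state$c_bn),
                       p$Wlbn, p$blbn, net$channels[net$depth])
  x <- st$h
  new_h_bn <- st$h; new_c_bn <- st$c
  for (k in rev(seq_len(net$depth))) {
    x <- ag_up2(x)
    x <- ag_cat_channels(x, skips[[k]])
    x <- ag_relu(ag_conv3(x, p[[paste0("Wd", k)]], p[[paste0("bd", k)]]))
  }
  st <- conv_lstm_step(x, ag_const(state$h_out), ag_const(state$c_out),
                       p$Wlout, p$blout, net$channels[1])
  x <- st$h
  new_h_out <- st$h; new_c_out <- st$c
  logits <- ag_conv3(x, p$Whead, p$bhead)
  list(logits = logits,
       state = list(h_in = new_h_in$val, c_in = new_c_in$val,
                    h_bn = new_h_bn$val, c_bn = new_c_bn$val,
                    h_out = new_h_out$val, c_out = new_c_out$val))
}

#' Run the posture network on a crop
#'
#' @param net a `heatmap_network`.
#' @param crop numeric matrix (`input_size` square), any intensity scale;
#'   normalised internally.
#' @param update_state carry the recurrent state to the next call; with
#'   `FALSE` (or after [reset_state()]) identical crops give identical
#'   outputs.
#' @return list with `heat` (H x W x 2 array; each channel sums to 1),
#'   `head`, `tail` (px, subpixel), `confidence` (per-keypoint peak mass
#'   in a 5x5 window).
#' @export
predict_heatmap <- function(net, crop, update_state = TRUE) {
  stopifnot(inherits(net, "heatmap_network"),
            all(dim(crop) == net$input_size))
  crop <- crop / max(max(crop), 1)
  fw <- heatmap_forward(net, crop, net$state)
  if (update_state) net$state <- fw$state
  lg <- fw$logits$val
  heat <- array(0, dim(lg))
  heat[, , 1] <- spatial_softmax(lg[, , 1])
  heat[, , 2] <- spatial_softmax(lg[, , 2])
  kh <- decode_keypoint(heat[, , 1])
  kt <- decode_keypoint(heat[, , 2])
  list(heat = heat, head = kh$xy, tail = kt$xy,
       confidence = c(head = kh$conf, tail = kt$conf))
}

# argmax with quadratic subpixel refinement; confidence = probability
# mass in the 5x5 window around the peak
decode_keypoint <- function(pm) {
  ij <- which(pm == max(pm), arr.ind = TRUE)[1, ]
  refine <- function(m, i, n) {
    if (i <= 1 || i >= n) return(0)
    lm <- log(pmax(m, 1e-12))
    den <- lm[1] - 2 * lm[2] + lm[3]
    if (abs(den) < 1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (lm[1] - lm[3]) / den))
  }
  dx <- refine(pm[max(1, ij[1] - 1):min(nrow(pm), ij[1] + 1), ij[2]],
               ij[1], nrow(pm))
  dy <- refine(pm[ij[1], max(1, ij[2] - 1):min(ncol(pm), ij[2] + 1)],
               ij[2], ncol(pm))
  i0 <- max(1, ij[1] - 2):min(nrow(pm), ij[1] + 2)
  j0 <- max(1, ij[2] - 2):min(ncol(pm), ij[2] + 2)
  list(xy = c(ij[1] - 0.5 + dx, ij[2] - 0.5 + dy),
       conf = sum(pm[i0, j0]))
}

# Gaussian target map centred on a keypoint, normalised to sum to 1
keypoint_target <- function(n, xy, sigma = 1.5) {
  g <- outer((seq_len(n) - 0.5 - xy[1])^2, (seq_len(n) - 0.5 - xy[2])^2,
             "+")
  g <- exp(-g / (2 * sigma^2))
  g / sum(g)
}

#' Train the posture network on labelled crops
#'
#' Single-frame training (recurrent state reset per sample): the loss is
#' the cross-entropy between each spatial softmax channel and a Gaussian
#' target map centred on the true keypoint.
#'
#' @param net a `heatmap_network`.
#' @param crops list of square matrices.
#' @param keypoints list of lists with `head` and `tail` positions (px).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param sigma target-map SD in px.
#' @return numeric vector of mean per-epoch losses.
#' @export
train_heatmap_network <- function(net, crops, keypoints, epochs = 2,
                                  lr = 2e-3, sigma = 1.5) {
  stopifnot(length(crops) == length(keypoints))
  st <- adam_state(net$params, lr = lr)
  n <- net$input_size
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in seq_along(crops)) {
      crop <- crops[[i]] / max(max(crops[[i]]), 1)
      fw <- heatmap_forward(net, crop, NULL)
      th <- keypoint_target(n, keypoints[[i]]$head, sigma)
      tt <- keypoint_target(n, keypoints[[i]]$tail, sigma)
      lh <- ag_spatial_xent(ag_channels(fw$logits, 1, 1),
                            array(th, c(n, n, 1)))
      lt <- ag_spatial_xent(ag_channels(fw$logits, 2, 2),
                            array(tt, c(n, n, 1)))
      loss <- ag_add(lh, lt)
      ag_backward(loss)
      st <- adam_step(st)
      tot <- tot + loss$val
    }
    hist[ep] <- tot / length(crops)
  }
  hist
}

#' Mean keypoint error of the posture network on labelled crops
#'
#' @inheritParams train_heatmap_network
#' @return mean Euclidean error in px over head and tail keypoints.
#' @export
keypoint_error <- function(net, crops, keypoints) {
  errs <- vapply(seq_along(crops), function(i) {
    pr <- predict_heatmap(net, crops[[i]], update_state = FALSE)
    (sqrt(sum((pr$head - keypoints[[i]]$head)^2)) +
       sqrt(sum((pr$tail - keypoints[[i]]$tail)^2))) / 2
  }, numeric(1))
  mean(errs)
}
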