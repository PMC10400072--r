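# Recurrent dense network for per-frame run/turn classification: nine
# densely connected linear layers alternating with ReLU, plus a
# bidirectional LSTM at the beginning and the middle of the sequence
# (11 layers in total), ending in a softmax over states. Training weights
# the loss 10-fold toward turn frames (runs dominate the data);
# inference applies an explicit switching cost before state selection.

# LSTM over a sequence; xs = list of 1 x d nodes; returns list of 1 x h
lstm_seq <- function(xs, W, b, h) {
  T <- length(xs)
  hs <- vector("list", T)
  h_prev <- ag_const(matrix(0, 1, h))
  c_prev <- ag_const(matrix(0, 1, h))
  for (t in seq_len(T)) {
    z <- ag_add_bias(ag_matmul(ag_cbind(xs[[t]], h_prev), W), b)
    i <- ag_sigmoid(ag_cols(z, 1, h))
    f <- ag_sigmoid(ag_cols(z, h + 1, 2 * h))
    o <- ag_sigmoid(ag_cols(z, 2 * h + 1, 3 * h))
    g <- ag_tanh(ag_cols(z, 3 * h + 1, 4 * h))
    c_prev <- ag_add(ag_mul(f, c_prev), ag_mul(i, g))
    h_prev <- ag_mul(o, ag_tanh(c_prev))
    hs[[t]] <- h_prev
  }
  hs
}

# bidirectional LSTM: concat of forward and reversed-backward passes;
# input a matrix node [T, d]; output matrix node [T, 2h]
bilstm <- function(x, Wf, bf, Wb, bb, h) {
  T <- nrow(x$val)
  xs <- lapply(seq_len(T), function(t) ag_row(x, t))
  hf <- lstm_seq(xs, Wf, bf, h)
  hb <- rev(lstm_seq(rev(xs), Wb, bb, h))
  ag_rbind(lapply(seq_len(T), function(t) ag_cbind(hf[[t]], hb[[t]])))
}

#' Build the behavioural state classifier network
#'
#' Nine dense linear layers alternating with ReLU activations and a
#' bidirectional LSTM at the beginning and middle of the stack (11
#' layers), followed by a softmax over behavioural states. The
#' bidirectional recurrence lets the network use frames both before and
#' after the current one.
#'
#' @param n_features per-frame input features.
#' @param hidden hidden width of the dense and LSTM layers.
#' @param n_states number of behavioural states (run, turn).
#' @param seed RNG seed for initialisation.
#' @return an object of class `state_network`.
#' @export
build_state_network <- function(n_features, hidden = 16, n_states = 2,
                                seed = 1) {
  stopifnot(n_features >= 1, hidden >= 2, n_states >= 2)
  set.seed(seed)
  h <- hidden
  p <- list()
  lstm_par <- function(d) {
    list(W = ag_param(ag_init(d + h, 4 * h, d + h)),
         b = ag_param(numeric(4 * h)))
  }
  p$l1f <- lstm_par(n_features); p$l1b <- lstm_par(n_features)
  dims <- c(2 * h, rep(h, 4))    # dense 1..4 after first BiLSTM
  for (k in 1:4) {
    p[[paste0("Wd", k)]] <- ag_param(ag_init(dims[k], dims[k + 1]))
    p[[paste0("bd", k)]] <- ag_param(numeric(dims[k + 1]))
  }
  p$l2f <- lstm_par(h); p$l2b <- lstm_par(h)
  dims2 <- c(2 * h, rep(h, 4))   # dense 5..8 after middle BiLSTM
  for (k in 1:4) {
    p[[paste0("Wd", k + 4)]] <- ag_param(ag_init(dims2[k], dims2[k + 1]))
    p[[paste0("bd", k + 4)]] <- ag_param(numeric(dims2[k + 1]))
  }
  p$Wd9 <- ag_param(ag_init(h, n_states))
  p$bd9 <- ag_param(numeric(n_states))
  net <- new.env(parent = emptyenv())
  net$params <- p
  net$n_features <- n_features
  net$hidden <- h
  net$n_states <- n_states
  class(net) <- "state_network"
  net
}

state_net_forward <- function(net, features) {
  p <- net$params
  h <- net$hidden
  x <- ag_const(features)
  x <- bilstm(x, p$l1f$W, p$l1f$b, p$l1b$W, p$l1b$b, h)
  for (k in 1:4) {
    x <- ag_relu(ag_add_bias(ag_matmul(x, p[[paste0("Wd", k)]]),
                             p[[paste0("bd", k)]]))
  }
  x <- bilstm(x, p$l2f$W, p$l2f$b, p$l2b$W, p$l2b$b, h)
  for (k in 5:8) {
    x <- ag_relu(ag_add_bias(ag_matmul(x, p[[paste0("Wd", k)]]),
                             p[[paste0("bd", k)]]))
  }
  ag_add_bias(ag_matmul(x, p$Wd9), p$bd9)
}

#' Per-frame state probabilities from the classifier network
#'
#' @param net a `state_network`.
#' @param features matrix [frames, n_features].
#' @return matrix [frames, n_states] of softmax probabilities (rows sum
#'   to 1).
#' @export
predict_state_probs <- function(net, features) {
  stopifnot(inherits(net, "state_network"),
            ncol(features) == net$n_features)
  z <- state_net_forward(net, features)$val
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Classify states with the network and a switching cost
#'
#' Runs the network, then decodes the state sequence with
#' [apply_switching_cost()] rather than taking the per-frame argmax.
#'
#' @inheritParams predict_state_probs
#' @param switching_cost per-transition penalty (natural-log units).
#' @param states state labels, first = run.
#' @return character vector of per-frame states.
#' @export
predict_states <- function(net, features, switching_cost = 2,
                           states = c("run", "turn")) {
  probs <- predict_state_probs(net, features)
  states[apply_switching_cost(probs, switching_cost)]
}

#' Train the state classifier on labelled sequences
#'
#' Cross-entropy loss with 10-fold weight on turn frames, since the
#' animal crawls forward in the large majority of frames.
#'
#' @param net a `state_network`.
#' @param sequences list of feature matrices [frames, n_features].
#' @param labels list of integer vectors (1 = run, 2 = turn, ...).
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param turn_weight loss weight of non-run frames.
#' @return numeric vector of mean per-epoch losses.
#' @export
train_state_network <- function(net, sequences, labels, epochs = 5,
                                lr = 5e-3, turn_weight = 10) {
  stopifnot(length(sequences) == length(labels))
  st <- adam_state(net$params, lr = lr)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (i in seq_along(sequences)) {
      lab <- labels[[i]]
      target <- matrix(0, length(lab), net$n_states)
      target[cbind(seq_along(lab), lab)] <- 1
      w <- ifelse(lab != 1, turn_weight, 1)
      logits <- state_net_forward(net, sequences[[i]])
      loss <- ag_softmax_xent(logits, target, w)
      ag_backward(loss)
      st <- adam_step(st)
      tot <- tot + loss$val
    }
    hist[ep] <- tot / length(sequences)
  }
  hist
}
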