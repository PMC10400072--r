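# Minimal reverse-mode automatic differentiation engine used by the two
# small neural networks in this package (the heatmap posture network and
# the behavioural state classifier). Values are numeric vectors, matrices
# or 3-D arrays [H, W, C]; the graph is built dynamically and
# differentiated by iterative topological traversal.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(val, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "ag_node"
  e
}

#' @keywords internal
ag_const <- function(val) ag_node(val)

# a parameter is just a node the optimiser knows about
ag_param <- function(val) ag_node(val)

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

zeros_like <- function(v) {
  if (is.null(dim(v))) numeric(length(v)) else array(0, dim(v))
}

# ---- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$val + b$val, list(a, b), function(g) list(g, g))
}

# add a per-column bias vector to a matrix [n, d]
ag_add_bias <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(sweep(a$val, 2, b$val, "+"), list(a, b),
          function(g) list(g, colSums(g)))
}

# add a per-channel bias to an array [H, W, C]
ag_add_cbias <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  d <- dim(a$val)
  ag_node(a$val + rep(b$val, each = d[1] * d[2]), list(a, b),
          function(g) list(g, apply(g, 3, sum)))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$val * b$val, list(a, b),
          function(g) list(g * b$val, g * a$val))
}

ag_relu <- function(a) {
  a <- as_node(a)
  m <- a$val > 0
  ag_node(a$val * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$val))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  a <- as_node(a)
  th <- tanh(a$val)
  ag_node(th, list(a), function(g) list(g * (1 - th^2)))
}

# ---- linear algebra -------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_node(a$val %*% b$val, list(a, b),
          function(g) list(g %*% t(b$val), crossprod(a$val, g)))
}

ag_cbind <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  na <- ncol(a$val)
  ag_node(cbind(a$val, b$val), list(a, b),
          function(g) list(g[, seq_len(na), drop = FALSE],
                           g[, -seq_len(na), drop = FALSE]))
}

# stack a list of row vectors (or 1-row matrices) into a matrix [T, d]
ag_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- do.call(rbind, lapply(nodes, function(n) as.vector(n$val)))
  ag_node(vals, nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      gi <- g[i, ]
      if (!is.null(dim(nodes[[i]]$val))) dim(gi) <- dim(nodes[[i]]$val)
      gi
    })
  })
}

# ---- convolutional ops on [H, W, C] arrays --------------------------------

# cached im2col index tables keyed by H x W x C (3x3 kernel, zero pad 1)
im2col_index <- function(h, w, cin) {
  key <- paste(h, w, cin, sep = "x")
  if (!is.null(.ag[[key]])) return(.ag[[key]])
  # padded array has (h+2) x (w+2); build linear indices into it for each
  # of the 9 kernel taps and each channel
  hp <- h + 2L
  px <- rep(seq_len(h), times = w)       # row of output pixel
  py <- rep(seq_len(w), each = h)
  taps <- expand.grid(di = 0:2, dj = 0:2)
  cols <- matrix(0L, h * w, 9L * cin)
  for (k in seq_len(9)) {
    di <- taps$di[k]; dj <- taps$dj[k]
    base <- (py + dj - 1L) * hp + (px + di)
    for (c in seq_len(cin)) {
      cols[, (k - 1L) * cin + c] <- base + (c - 1L) * hp * (w + 2L)
    }
  }
  .ag[[key]] <- cols
  cols
}

# 3x3 same-padding convolution: x [H,W,Cin], w [9*Cin, Cout], b [Cout]
ag_conv3 <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  d <- dim(x$val); h <- d[1]; wd <- d[2]; cin <- d[3]
  cout <- ncol(w$val)
  idx <- im2col_index(h, wd, cin)
  padded <- array(0, c(h + 2L, wd + 2L, cin))
  padded[2:(h + 1), 2:(wd + 1), ] <- x$val
  cols <- matrix(padded[idx], nrow = h * wd)
  out <- cols %*% w$val
  out <- sweep(out, 2, b$val, "+")
  dim(out) <- c(h, wd, cout)
  ag_node(out, list(x, w, b), function(g) {
    gm <- matrix(g, nrow = h * wd)
    gw <- crossprod(cols, gm)
    gb <- colSums(gm)
    gcols <- gm %*% t(w$val)             # [HW, 9*Cin]
    gpad <- array(0, c(h + 2L, wd + 2L, cin))
    # scatter-add back through the index table
    for (k in seq_len(ncol(idx))) {
      ii <- idx[, k]
      gpad[ii] <- gpad[ii] + gcols[, k]
    }
    gx <- gpad[2:(h + 1), 2:(wd + 1), , drop = FALSE]
    dim(gx) <- c(h, wd, cin)
    list(gx, gw, gb)
  })
}

# 2x2 max pooling (H, W even)
ag_pool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$val); h <- d[1]; w <- d[2]; ch <- d[3]
  a11 <- x$val[seq(1, h, 2), seq(1, w, 2), , drop = FALSE]
  a21 <- x$val[seq(2, h, 2), seq(1, w, 2), , drop = FALSE]
  a12 <- x$val[seq(1, h, 2), seq(2, w, 2), , drop = FALSE]
  a22 <- x$val[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
  out <- pmax(a11, a21, a12, a22)
  ag_node(out, list(x), function(g) {
    gx <- array(0, d)
    # route gradient to the (first) argmax of each 2x2 block
    pick <- function(sel, ai) (ai == out) & sel
    remaining <- array(TRUE, dim(out))
    for (blk in list(list(1, 1, a11), list(2, 1, a21),
                     list(1, 2, a12), list(2, 2, a22))) {
      sel <- pick(remaining, blk[[3]])
      remaining <- remaining & !sel
      gi <- g * sel
      gx[seq(blk[[1]], h, 2), seq(blk[[2]], w, 2), ] <-
        gx[seq(blk[[1]], h, 2), seq(blk[[2]], w, 2), ] + gi
    }
    list(gx)
  })
}

# 2x nearest-neighbour upsampling
ag_up2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$val); h <- d[1]; w <- d[2]; ch <- d[3]
  ri <- rep(seq_len(h), each = 2); ci <- rep(seq_len(w), each = 2)
  out <- x$val[ri, ci, , drop = FALSE]
  ag_node(out, list(x), function(g) {
    gx <- g[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
      g[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE] +
      g[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE] +
      g[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]
    list(gx)
  })
}

ag_cat_channels <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  da <- dim(a$val); db <- dim(b$val)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a$val
  out[, , da[3] + seq_len(db[3])] <- b$val
  ag_node(out, list(a, b), function(g)
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE]))
}

ag_channels <- function(x, from, to) {
  x <- as_node(x)
  d <- dim(x$val)
  ag_node(x$val[, , from:to, drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[, , from:to] <- g
    list(gx)
  })
}

# column slice of a matrix node
ag_cols <- function(x, from, to) {
  x <- as_node(x)
  d <- dim(x$val)
  ag_node(x$val[, from:to, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[, from:to] <- g
    list(gx)
  })
}

# single-row slice of a matrix node (kept as a 1 x d matrix)
ag_row <- function(x, i) {
  x <- as_node(x)
  d <- dim(x$val)
  ag_node(x$val[i, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[i, ] <- g
    list(gx)
  })
}

# ---- losses ---------------------------------------------------------------

# rowwise softmax cross-entropy with per-row weights; target is a
# one-hot (or soft) matrix of the same shape as logits
ag_softmax_xent <- function(logits, target, weights = NULL) {
  logits <- as_node(logits)
  z <- logits$val
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  if (is.null(weights)) weights <- rep(1, nrow(z))
  wsum <- sum(weights)
  loss <- -sum(weights * rowSums(target * log(pmax(p, 1e-12)))) / wsum
  ag_node(loss, list(logits), function(g)
    list(g * (p - target) * (weights / wsum)))
}

# spatial softmax cross-entropy over one channel: flattens [H, W] to a
# distribution and compares to a target map summing to 1
ag_spatial_xent <- function(logit_map, target_map) {
  logit_map <- as_node(logit_map)
  z <- as.vector(logit_map$val)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  loss <- -sum(as.vector(target_map) * log(pmax(p, 1e-12)))
  d <- dim(logit_map$val)
  ag_node(loss, list(logit_map), function(g) {
    gx <- g * (p - as.vector(target_map))
    dim(gx) <- d
    list(gx)
  })
}

# spatial softmax (inference): normalises a [H, W] map to sum to 1
spatial_softmax <- function(m) {
  z <- m - max(m)
  p <- exp(z)
  p / sum(p)
}

# ---- backward pass and optimiser ------------------------------------------

# iterative topological sort + reverse accumulation
ag_backward <- function(root) {
  order <- vector("list", 256); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L)); nstack <- 1L
  while (nstack > 0L) {
    top <- stack[[nstack]]
    if (top$stage == 1L) {
      key <- as.character(top$node$id)
      if (!is.null(seen[[key]])) { nstack <- nstack - 1L; next }
      seen[[key]] <- TRUE
      stack[[nstack]]$stage <- 2L
      for (p in top$node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          nstack <- nstack + 1L
          stack[[nstack]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", norder))
      order[[norder]] <- top$node
      nstack <- nstack - 1L
    }
  }
  for (i in seq_len(norder)) order[[i]]$grad <- NULL
  root$grad <- if (is.null(dim(root$val))) rep(1, length(root$val)) else
    array(1, dim(root$val))
  for (i in rev(seq_len(norder))) {
    n <- order[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}

# Adam optimiser state over a flat list of ag_param nodes
adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) zeros_like(p$val)),
       v = lapply(params, function(p) zeros_like(p$val)),
       t = 0L)
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    mhat <- st$m[[i]] / (1 - st$beta1^st$t)
    vhat <- st$v[[i]] / (1 - st$beta2^st$t)
    p$val <- p$val - st$lr * mhat / (sqrt(vhat) + st$eps)
    p$grad <- NULL
  }
  st
}

# He-scaled random init
ag_init <- function(nr, nc, fan_in = nr) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
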