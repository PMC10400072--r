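# Linking loss, greedy assignment, interpolation, collisions.

mk_det <- function(x, y, a = 30) {
  list(centroid = c(x, y), area = a)
}

test_that("linking loss satisfies its stated identities", {
  cfg <- linking_config(beta_r = 1, beta_p = 0.5, beta_a = 0.01)
  tr <- track_state(1, r = c(10, 10), p = c(0, 0), a = 30)
  expect_equal(link_loss(mk_det(10, 10, 30), tr, cfg), 0)
  cfg2 <- linking_config(beta_r = 1, beta_p = 0, beta_a = 0)
  expect_equal(link_loss(mk_det(13, 14, 30), tr, cfg2), 5)  # 3-4-5
})

test_that("linking loss matches an independently coded formula", {
  set.seed(21)
  for (case in 1:1000) {
    b <- runif(3, 0, 2)
    cfg <- linking_config(beta_r = b[1], beta_p = b[2], beta_a = b[3])
    r_t <- runif(2, 0, 100); p_t <- runif(2, -3, 3)
    a_t <- runif(1, 10, 60)
    d <- mk_det(runif(1, 0, 100), runif(1, 0, 100), runif(1, 10, 60))
    tr <- track_state(1, r_t, p_t, a_t)
    # brute-force re-evaluation from the definition
    pd <- c(d$centroid[1] - r_t[1], d$centroid[2] - r_t[2])
    want <- b[1] * sqrt(sum((d$centroid - r_t)^2)) +
      b[2] * sqrt((pd[1] - p_t[1])^2 + (pd[2] - p_t[2])^2) +
      b[3] * abs(d$area - a_t)
    expect_equal(link_loss(d, tr, cfg), want, tolerance = 1e-12)
  }
})

test_that("assignment is greedy, not globally optimal", {
  # losses [[1, 2], [3, 100]]: greedy takes (t1,d1) then (t2,d2) for a
  # total of 101, although (t1,d2)+(t2,d1) would total 5
  cfg <- linking_config(beta_r = 1, beta_p = 0, beta_a = 0,
                        max_loss = 1000)
  tracks <- list(track_state(1, c(0, 0)), track_state(2, c(0, 3)))
  dets <- list(mk_det(0, 1), mk_det(0, 103))
  # check the constructed loss matrix is the intended one
  expect_equal(link_loss(dets[[1]], tracks[[1]], cfg), 1)
  expect_equal(link_loss(dets[[2]], tracks[[1]], cfg), 103)
  expect_equal(link_loss(dets[[1]], tracks[[2]], cfg), 2)
  expect_equal(link_loss(dets[[2]], tracks[[2]], cfg), 100)
  asg <- assign_identities(dets, tracks, cfg)
  m <- asg$matches[order(asg$matches$track_idx), ]
  expect_equal(m$det_idx, c(1, 2))
  expect_equal(sum(m$loss), 101)
})

test_that("assignment gates on max_loss and is deterministic", {
  cfg <- linking_config(max_loss = 5)
  tracks <- list(track_state(1, c(0, 0)))
  expect_equal(nrow(assign_identities(list(mk_det(1, 0, 30)),
                                      lapply(tracks, function(t) {
                                        t$a <- 30; t
                                      }), cfg)$matches), 1)
  far <- assign_identities(list(mk_det(100, 0)), tracks, cfg)
  expect_equal(nrow(far$matches), 0)
  expect_equal(far$unmatched_tracks, 1L)
  expect_equal(far$unmatched_dets, 1L)
  # exact ties break toward the lower track id
  cfg2 <- linking_config(beta_r = 1, beta_p = 0, beta_a = 0,
                         max_loss = 100)
  tracks2 <- list(track_state(7, c(0, 2)), track_state(3, c(0, -2)))
  asg <- assign_identities(list(mk_det(0, 0)), tracks2, cfg2)
  expect_equal(tracks2[[asg$matches$track_idx]]$id, 3L)
  asg_b <- assign_identities(list(mk_det(0, 0)), tracks2, cfg2)
  expect_identical(asg, asg_b)
})

test_that("greedy agrees with an independent oracle on random cases", {
  # oracle: repeatedly scan the full loss matrix for the smallest
  # remaining entry (ties: lower track id, then detection index)
  set.seed(22)
  cfg <- linking_config(beta_r = 1, beta_p = 0.3, beta_a = 0.05,
                        max_loss = 1e6)
  for (case in 1:50) {
    nt <- sample(1:5, 1); nd <- sample(1:5, 1)
    tracks <- lapply(seq_len(nt), function(i)
      track_state(i, runif(2, 0, 50), runif(2, -2, 2), runif(1, 10, 50)))
    dets <- lapply(seq_len(nd), function(j)
      mk_det(runif(1, 0, 50), runif(1, 0, 50), runif(1, 10, 50)))
    L <- outer(seq_len(nt), seq_len(nd),
               Vectorize(function(i, j) link_loss(dets[[j]], tracks[[i]],
                                                  cfg)))
    pairs <- list()
    Lw <- L
    while (any(is.finite(Lw))) {
      ij <- which(Lw == min(Lw), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
      pairs[[length(pairs) + 1]] <- ij
      Lw[ij[1], ] <- Inf; Lw[, ij[2]] <- Inf
    }
    want <- do.call(rbind, pairs)
    got <- assign_identities(dets, tracks, cfg)$matches
    got <- as.matrix(got[order(got$loss), c("track_idx", "det_idx")])
    expect_equal(unname(got), unname(want[order(L[want]), , drop = FALSE]))
  }
})

test_that("gap interpolation is linear and flagged", {
  tr <- data.frame(frame = c(5, 10), x = c(0, 10), y = c(0, 0))
  fill <- interpolate_gaps(tr, 6:9)
  expect_equal(fill$x, c(2, 4, 6, 8))
  expect_equal(fill$y, rep(0, 4))
  expect_true(all(fill$interpolated))
  expect_equal(nrow(interpolate_gaps(tr, integer(0))), 0)
  expect_error(interpolate_gaps(tr, 6:9, max_gap = 3), "max_gap")
})

test_that("collision opens only for oversized multi-track detections", {
  tracks <- list(track_state(1, c(10, 10), p = c(1, 0)),
                 track_state(2, c(14, 10), p = c(-1, 0)))
  big <- list(list(centroid = c(12, 10), area = 80,
                   bbox = c(8, 16, 7, 13), frame = 5L))
  ev <- detect_collision(big, tracks, max_single_area = 45)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$ids, c(1L, 2L))
  # a small detection never opens a collision
  small <- list(list(centroid = c(12, 10), area = 30,
                     bbox = c(10, 14, 8, 12), frame = 5L))
  expect_length(detect_collision(small, tracks, 45), 0)
  # distant predicted positions do not participate
  far <- list(track_state(1, c(100, 100)), track_state(2, c(200, 200)))
  expect_length(detect_collision(big, far, 45), 0)
})

test_that("perfect-overlap collisions recover the exact offsets", {
  blob <- matrix(FALSE, 7, 7); blob[2:6, 3:5] <- TRUE
  off1 <- c(10, 10); off2 <- c(16, 11)
  shift1 <- c(2, 1); shift2 <- c(-2, 0)
  canvas <- matrix(FALSE, 40, 40)
  canvas <- larvatrack:::paint_mask(canvas, blob, off1 + shift1)
  canvas <- larvatrack:::paint_mask(canvas, blob, off2 + shift2)
  idx <- which(canvas, arr.ind = TRUE)
  bb <- c(range(idx[, 1]), range(idx[, 2]))
  merged <- list(mask = canvas[bb[1]:bb[2], bb[3]:bb[4]],
                 offset = c(bb[1] - 1L, bb[3] - 1L))
  priors <- list(
    list(mask = blob, offset = off1, centroid = off1 + c(4, 4) - 0.5,
         momentum = c(1, 1)),
    list(mask = blob, offset = off2, centroid = off2 + c(4, 4) - 0.5,
         momentum = c(-1, 0)))
  res <- resolve_collision(priors, merged, max_epochs = 50)
  expect_equal(res$status, "resolved")
  expect_equal(unname(round(unlist(res$translations))),
               c(shift1, shift2))
  # single-participant degenerate case reduces to a translation match
  merged1 <- list(mask = blob, offset = off1 + shift1)
  res1 <- resolve_collision(priors[1], merged1, max_epochs = 50)
  expect_equal(unname(round(unlist(res1$translations))), shift1)
})
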