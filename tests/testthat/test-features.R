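# Trajectory features: speed, turn rate, curvature, handedness,
# navigation index, stitching, peri-event averages.

mk_track <- function(x, y, fr = 10) {
  n <- length(x)
  data.frame(frame = 1:n, time = (1:n - 1) / fr, id = 1, x = x, y = y,
             interpolated = FALSE)
}

test_that("speed of uniform motion and of rest are exact", {
  tr <- mk_track(0.5 * (1:100), rep(0, 100))
  sp <- compute_speed(tr, window = 1, frame_rate = 10)
  expect_equal(sp, rep(5, 100))
  sp0 <- compute_speed(mk_track(rep(1, 50), rep(2, 50)), 1, 10)
  expect_equal(sp0, rep(0, 50))
  expect_error(compute_speed(tr, window = 0.05, frame_rate = 10),
               "2 frames")
})

test_that("a simulated speed decay is recovered by regression", {
  cfg <- clean_sim_config(n_animals = 1, duration = 1800, seed = 51,
                          mean_speed = 0.6, speed_decay = -1e-4)
  tr <- simulate_trajectories(cfg)
  tf <- truth_as_track(tr)
  sp <- compute_speed(tf, window = 1, frame_rate = 10)
  run <- tf$state == "run" & is.finite(sp)
  fit <- lm(sp[run] ~ tf$time[run])
  expect_lt(abs(coef(fit)[2] - cfg$speed_decay) / abs(cfg$speed_decay),
            0.1)
})

test_that("turn rate counts events per minute in a sliding window", {
  expect_equal(compute_turn_rate(data.frame(onset_s = numeric(0)),
                                 times = c(10, 50), window = 60),
               c(0, 0))
  set.seed(52)
  lambda <- 4  # per minute
  ev <- data.frame(onset_s = cumsum(rexp(400, lambda / 60)))
  rate <- compute_turn_rate(ev, times = seq(600, 4000, by = 60),
                            window = 300)
  expect_lt(abs(mean(rate) - lambda), 3 * sd(rate) / sqrt(length(rate)))
})

test_that("curvature of canonical paths is exact", {
  line <- cbind(seq(0, 50, 0.5), 0)
  expect_true(all(abs(compute_curvature(line, 1)$curvature) < 1e-9))
  th <- seq(0, 4 * pi, length.out = 2000)
  R <- 7
  circ <- cbind(R * cos(th), R * sin(th))   # counter-clockwise
  cv <- compute_curvature(circ, arc_step = 1)$curvature
  expect_equal(mean(cv), 1 / R, tolerance = 0.02)
  # clockwise circle has negative curvature (right-bending)
  cw <- cbind(R * cos(-th), R * sin(-th))
  expect_lt(mean(compute_curvature(cw, 1)$curvature), 0)
  expect_error(compute_curvature(line[1:2, ], 1), "3 arc steps")
})

test_that("handedness follows its defining formula", {
  mk_ev <- function(nl, nr) data.frame(
    direction = c(rep("left", nl), rep("right", nr)),
    size_deg = c(rep(30, nl), rep(-30, nr)))
  expect_equal(turn_handedness(mk_ev(10, 0))$handedness, 1)
  expect_equal(turn_handedness(mk_ev(0, 10))$handedness, -1)
  expect_equal(turn_handedness(mk_ev(7, 3))$handedness, 0.4)
  h0 <- turn_handedness(mk_ev(0, 0))
  expect_true(is.na(h0$handedness))
  # ambiguous turns are excluded but counted
  ev <- mk_ev(3, 1); ev$direction[2] <- NA
  h <- turn_handedness(ev)
  expect_equal(h$n_total, 3)
  expect_equal(h$n_ambiguous, 1)
})

test_that("handedness is antisymmetric under mirroring", {
  cfg <- clean_sim_config(n_animals = 1, duration = 900, seed = 53,
                          handedness_bias = 0.5)
  tr <- simulate_trajectories(cfg)
  bs <- classify_behavior(truth_as_track(tr), frame_rate = 10)
  tf_m <- truth_as_track(tr)
  tf_m$y <- -tf_m$y; tf_m$bend <- -tf_m$bend   # mirror about x-axis
  bs_m <- classify_behavior(tf_m, frame_rate = 10)
  h <- turn_handedness(bs$events)$handedness
  hm <- turn_handedness(bs_m$events)$handedness
  expect_equal(h, -hm, tolerance = 1e-12)
  expect_gt(h, 0)
})

test_that("navigation index hits its analytic extremes", {
  straight <- mk_track(0.4 * (1:200), rep(3, 200))
  expect_equal(navigation_index(straight, frame_rate = 10)$overall, 1)
  back <- mk_track(-0.4 * (1:200), rep(3, 200))
  expect_equal(navigation_index(back, frame_rate = 10)$overall, -1)
  # closed loop over an integer number of periods
  th <- seq(0, 6 * pi, length.out = 1201)
  loop <- mk_track(10 * cos(th), 10 * sin(th))
  expect_lt(abs(navigation_index(loop, frame_rate = 10)$overall), 1e-6)
  # stationary track is undefined and flagged
  still <- mk_track(rep(0, 50), rep(0, 50))
  expect_true(is.na(navigation_index(still, frame_rate = 10)$overall))
})

test_that("|navigation index| <= 1 on arbitrary random walks", {
  set.seed(54)
  for (case in 1:25) {
    n <- sample(50:400, 1)
    tr <- mk_track(cumsum(rnorm(n)), cumsum(rnorm(n)))
    ni <- navigation_index(tr, frame_rate = 10)$overall
    expect_lte(abs(ni), 1)
  }
})

test_that("windowed navigation index flags empty windows", {
  tr <- mk_track(0.4 * (1:600), rep(0, 600))
  ni <- navigation_index(tr, window = 10, frame_rate = 10)
  expect_true(all(ni$series$index[ni$series$defined] == 1))
})

test_that("stitching translates segments into a continuous path", {
  # two straight 1 m segments, displaced by a relocation
  seg1 <- cbind(seq(0, 1000, by = 5), 0)
  seg2 <- cbind(seq(500, 1500, by = 5), 300)
  n1 <- nrow(seg1); n2 <- nrow(seg2)
  track <- data.frame(frame = c(1:n1, (n1 + 10):(n1 + 9 + n2)),
                      x = c(seg1[, 1], seg2[, 1]),
                      y = c(seg1[, 2], seg2[, 2]))
  events <- data.frame(type = "relocation", start_frame = n1,
                       end_frame = n1 + 10)
  st <- stitch_trajectory(track, events)
  expect_equal(st$length_m, 2, tolerance = 1e-9)
  # C0 continuity at the boundary
  i <- which(st$path$segment == 2)[1]
  expect_equal(st$path$x[i], st$path$x[i - 1])
  expect_equal(st$path$y[i], st$path$y[i - 1])
  # translation only: headings within segments unchanged
  dx2 <- diff(st$path$x[st$path$segment == 2])
  expect_equal(unique(round(dx2, 9)), 5)
  expect_equal(unique(st$path$y[st$path$segment == 2]),
               st$path$y[i - 1])
})

test_that("stitched length matches ground-truth crawl length within 1%", {
  cfg <- clean_sim_config(n_animals = 1, duration = 900, seed = 55,
                          occlusion_rate = 20, arena_side = 120)
  tr <- simulate_trajectories(cfg)
  expect_gt(nrow(tr$events), 0)
  tf <- tr$frames[tr$frames$id == 1, ]
  vis <- tf[tf$visible, ]
  st <- stitch_trajectory(vis, tr$events[tr$events$id == 1, ])
  # ground truth: crawled path length excluding relocation jumps
  seg <- st$path$segment
  true_len <- 0
  for (s in unique(seg)) {
    p <- vis[seg == s, ]
    true_len <- true_len + sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  }
  expect_lt(abs(st$length_m - true_len / 1000) / (true_len / 1000), 0.01)
})

test_that("peri-event averaging recovers a step transient", {
  dt <- 0.1
  times <- seq(0, 2000, by = dt)
  base <- rep(1, length(times))
  events <- c(500, 1000, 1500)
  tau <- 30
  for (et in events) {
    idx <- times >= et
    base[idx] <- base[idx] + 0.8 * exp(-(times[idx] - et) / tau)
  }
  pe <- perievent_average(times, base, events, before = 100, after = 200)
  expect_equal(pe$n_events, 3)
  # pre-event mean flat at the baseline
  expect_equal(mean(pe$mean[pe$lag < 0]), 1, tolerance = 1e-6)
  # recovered time constant within 20%: lag where the excess falls to 1/e
  excess <- pe$mean[pe$lag >= 0] - 1
  tau_hat <- pe$lag[pe$lag >= 0][which(excess <= 0.8 / exp(1))[1]]
  expect_lt(abs(tau_hat - tau) / tau, 0.2)
  # events at the series edge are excluded silently
  pe2 <- perievent_average(times, base, c(5, events), before = 100,
                           after = 200)
  expect_equal(pe2$n_events, 3)
  # constant series gives a flat average at the constant
  pc <- perievent_average(times, rep(2, length(times)), events, 50, 50)
  expect_true(all(abs(pc$mean - 2) < 1e-12))
})
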