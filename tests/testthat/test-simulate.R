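# Simulator: configuration validation, reproducibility, trajectory
# statistics and the Gaussian variability model.

test_that("configuration is validated", {
  expect_error(sim_config(handedness_bias = 1.5), "handedness_bias")
  expect_error(sim_config(turn_rate = -1), "non-negative")
  expect_error(sim_config(mean_speed = NaN), "finite")
  expect_error(sim_config(n_animals = 0), "n_animals")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical seeds give bit-identical trajectories and frames", {
  cfg <- clean_sim_config(n_animals = 2, duration = 10, seed = 42,
                          noise_sd = 2, background_drift = 0.05)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(t1, t2)
  s1 <- render_video(t1); s2 <- render_video(t2)
  expect_identical(s1$get(5), s2$get(5))
  # deterministic under random access order
  expect_identical(s1$get(3), s2$get(3))
})

test_that("zero turn rate gives a straight path of the expected length", {
  cfg <- clean_sim_config(n_animals = 1, duration = 30, seed = 3,
                          turn_rate = 0, speed_decay = 0,
                          run_heading_sd = 0)
  tr <- simulate_trajectories(cfg)
  tf <- tr$frames
  expect_equal(nrow(tr$turns), 0)
  expect_true(all(tf$state == "run"))
  len <- sum(sqrt(diff(tf$x)^2 + diff(tf$y)^2))
  # first frame records the starting position, so one step is missing
  expected <- cfg$mean_speed * cfg$duration
  expect_equal(len, expected, tolerance = 0.01)
})

test_that("full handedness bias makes every logged turn left-signed", {
  cfg <- clean_sim_config(n_animals = 2, duration = 300, seed = 4,
                          handedness_bias = 1)
  tr <- simulate_trajectories(cfg)
  expect_gt(nrow(tr$turns), 10)
  expect_true(all(tr$turns$size_deg > 0))
})

test_that("unbiased turns have near-zero mean signed size", {
  # ~2000 turns across animals; CLT bound at 3 standard errors
  cfg <- clean_sim_config(n_animals = 8, duration = 1500, seed = 5,
                          turn_rate = 12, turn_duration_mean = 1,
                          gradient_bias = 0, handedness_bias = 0)
  tr <- simulate_trajectories(cfg)
  n <- nrow(tr$turns)
  expect_gt(n, 1500)
  se <- sd(tr$turns$size_deg) / sqrt(n)
  expect_lt(abs(mean(tr$turns$size_deg)), 3 * se)
})

test_that("empirical turn rate converges to the configured rate", {
  cfg <- clean_sim_config(n_animals = 6, duration = 900, seed = 6,
                          turn_rate = 4)
  tr <- simulate_trajectories(cfg)
  n <- nrow(tr$turns)
  expected <- cfg$turn_rate * cfg$duration / 60 * cfg$n_animals
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("gradient bias tilts post-turn headings toward +x", {
  mk <- function(g, seed) {
    cfg <- clean_sim_config(n_animals = 8, duration = 600, seed = seed,
                            turn_rate = 6, gradient_bias = g)
    tf <- simulate_trajectories(cfg)$frames
    vapply(split(tf, tf$id), function(d)
      navigation_index(d, frame_rate = cfg$frame_rate)$overall,
      numeric(1))
  }
  ni_biased <- mk(2, seed = 7)
  ni_free <- mk(0, seed = 7)
  # biased walks drift up-gradient significantly; unbiased ones do not
  expect_gt(mean(ni_biased),
            3 * sd(ni_biased) / sqrt(length(ni_biased)))
  expect_lt(abs(mean(ni_free)), 3 * sd(ni_free) / sqrt(length(ni_free)))
  expect_gt(mean(ni_biased), mean(ni_free))
})

test_that("turn state alternates and logged turns lie in turn blocks", {
  cfg <- clean_sim_config(n_animals = 2, duration = 200, seed = 8)
  tr <- simulate_trajectories(cfg)
  for (i in unique(tr$frames$id)) {
    st <- tr$frames$state[tr$frames$id == i]
    r <- rle(st)
    expect_true(all(r$values %in% c("run", "turn")))
    expect_true(all(diff(match(r$values, c("run", "turn"))) != 0))
    turns_i <- tr$turns[tr$turns$id == i, ]
    for (k in seq_len(nrow(turns_i))) {
      span <- turns_i$onset_frame[k]:turns_i$offset_frame[k]
      expect_true(all(st[span] == "turn"))
    }
  }
})

test_that("occlusion events hide the animal and relocate it", {
  cfg <- clean_sim_config(n_animals = 1, duration = 600, seed = 9,
                          occlusion_rate = 20)
  tr <- simulate_trajectories(cfg)
  ev <- tr$events[tr$events$type == "relocation", ]
  expect_gt(nrow(ev), 0)
  e <- ev[1, ]
  tf <- tr$frames
  hidden <- tf$frame > e$start_frame & tf$frame < e$end_frame
  expect_true(all(!tf$visible[hidden]))
  # drop-off lands near the arena centre
  expect_lt(abs(e$x_after - cfg$arena_side / 2), 15)
})

test_that("variability model honours its degenerate limits", {
  m0 <- variability_model(8, 50, mu_population = 0.1, sigma_intra = 1,
                          sigma_inter = 0, rng_seed = 1)
  s0 <- simulate_variability(m0)
  expect_true(all(abs(s0$mu - 0.1) < 1e-12))
  m1 <- variability_model(8, 50, sigma_intra = 0, sigma_inter = 1,
                          rng_seed = 2)
  s1 <- simulate_variability(m1)
  expect_true(all(apply(s1$observations, 1, sd) == 0))
  expect_equal(dim(s1$observations), c(8L, 50L))
})

test_that("clustered means with small intra spread give a multimodal
           mean-of-intra density", {
  m <- variability_model(12, 200, sigma_intra = 0.05, sigma_inter = 0.02,
                         cluster_centers = c(-0.5, 0.5), rng_seed = 3)
  s <- simulate_variability(m)
  bc <- bimodality_coefficient(as.vector(s$observations))
  expect_gt(bc$bc, 5 / 9)
})
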