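# Bimodality coefficient, variability decomposition and two-sample
# helpers.

test_that("BC hits its distributional landmarks", {
  set.seed(61)
  u <- runif(1e5)
  expect_equal(bimodality_coefficient(u)$bc, 5 / 9, tolerance = 0.01)
  g <- rnorm(1e5)
  expect_equal(bimodality_coefficient(g)$bc, 1 / 3, tolerance = 0.01)
  # balanced mixture of two well-separated Gaussians (6 sigma apart)
  mix <- c(rnorm(5e3, -3), rnorm(5e3, 3))
  bcm <- bimodality_coefficient(mix)
  expect_gt(bcm$bc, 5 / 9)
  expect_true(bcm$is_bimodal)
})

test_that("BC is invariant under affine transforms", {
  set.seed(62)
  x <- rgamma(500, 2)
  b1 <- bimodality_coefficient(x)$bc
  b2 <- bimodality_coefficient(-3 + 7 * x)$bc
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("BC rejects degenerate inputs", {
  expect_error(bimodality_coefficient(c(1, 2, 3)), "at least 4")
  expect_error(bimodality_coefficient(rep(1, 10)), "variance")
})

test_that("low inter-animal variability: mean-of-intra matches the
           population density", {
  s <- simulate_variability(variability_model(
    10, 400, mu_population = 0.05, sigma_intra = 0.3, sigma_inter = 0,
    rng_seed = 63))
  dec <- intra_inter_decomposition(s$observations)
  # both densities integrate to 1
  dg <- diff(dec$grid[1:2])
  expect_equal(sum(dec$mean_intra) * dg, 1, tolerance = 0.02)
  expect_equal(sum(dec$population) * dg, 1, tolerance = 0.02)
  expect_equal(dec$inter_sd, sd(rowMeans(s$observations)))
  # the matched comparison: mean-of-intra agrees with the density of the
  # pooled observations when animals are interchangeable
  pooled <- density(as.vector(s$observations), from = dec$grid[1],
                    to = dec$grid[length(dec$grid)],
                    n = length(dec$grid))$y
  expect_lt(density_l1(dec$mean_intra, pooled, dec$grid), 0.1)
  # the per-timepoint-mean density is narrower by ~sqrt(n_animals) even
  # with zero inter-animal spread
  sd_pop <- sqrt(sum(dec$population * dec$grid^2 * dg) -
                   (sum(dec$population * dec$grid * dg))^2)
  expect_lt(sd_pop, 0.6 * dec$intra_sd)
})

test_that("two-cluster means: pooled BC is bimodal while every animal
           stays unimodal", {
  s <- simulate_variability(variability_model(
    12, 400, sigma_intra = 0.15, sigma_inter = 0.02,
    cluster_centers = c(-0.4, 0.4), rng_seed = 64))
  pooled <- bimodality_coefficient(rowMeans(s$observations))
  expect_gt(pooled$bc, 5 / 9)
  per_animal <- apply(s$observations, 1,
                      function(v) bimodality_coefficient(v)$bc)
  expect_true(all(per_animal <= 5 / 9))
})

test_that("identical animals have zero inter-animal SD", {
  row <- rnorm(100)
  obs <- matrix(rep(row, 5), nrow = 5, byrow = TRUE)
  dec <- intra_inter_decomposition(obs)
  expect_equal(dec$inter_sd, 0)
  expect_equal(dec$intra_sd, sd(row))
})

test_that("variance decomposes per the law of total variance", {
  s <- simulate_variability(variability_model(
    40, 400, sigma_intra = 0.5, sigma_inter = 0.3, rng_seed = 65))
  dec <- intra_inter_decomposition(s$observations)
  total <- var(as.vector(s$observations))
  expect_equal(total, dec$intra_sd^2 + dec$inter_sd^2, tolerance = 0.1)
})

test_that("t test and correlation behave on canonical inputs", {
  x <- c(1, 2, 3, 4, 5)
  tt <- two_sample_t(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  # hand-computed two-group fixture: a = (1,2,3), b = (3,4,5)
  # means 2 and 4, pooled var = 1, t = -2 / (1 * sqrt(2/3)) = -2.449...
  tt2 <- two_sample_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(tt2$t, -2 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(tt2$cohens_d, -2)
  a <- rnorm(50)
  expect_equal(series_correlation(a, a), 1)
  expect_equal(series_correlation(a, -a), -1)
  expect_error(series_correlation(a, rep(1, 50)), "constant")
})

test_that("an injected mean shift is detected at alpha = 0.01", {
  sa <- simulate_variability(variability_model(
    20, 100, mu_population = 0.13, sigma_intra = 0.3, sigma_inter = 0.05,
    rng_seed = 66))
  sb <- simulate_variability(variability_model(
    20, 100, mu_population = 0.03, sigma_intra = 0.3, sigma_inter = 0.05,
    rng_seed = 67))
  tt <- two_sample_t(rowMeans(sa$observations),
                     rowMeans(sb$observations))
  expect_lt(tt$p_value, 0.01)
  expect_gt(tt$mean_a, tt$mean_b)
})

test_that("bootstrap BC comparison separates the two regimes", {
  uni <- simulate_variability(variability_model(
    14, 300, sigma_intra = 0.3, sigma_inter = 0.03, rng_seed = 68))
  bim <- simulate_variability(variability_model(
    14, 300, sigma_intra = 0.15, sigma_inter = 0.03,
    cluster_centers = c(-0.4, 0.4), rng_seed = 69))
  res <- bc_bootstrap_test(bim$observations, uni$observations,
                           n_boot = 200, seed = 70)
  expect_gt(res$bc_a, 5 / 9)
  expect_lt(res$bc_b, 5 / 9)
  expect_lt(res$p_value, 0.05)
})

test_that("correlated speed and turn-rate decay yields positive r", {
  cfg <- clean_sim_config(n_animals = 2, duration = 1800, seed = 71,
                          mean_speed = 0.7, speed_decay = -2e-4,
                          turn_rate = 4)
  tr <- simulate_trajectories(cfg)
  tf <- truth_as_track(tr)
  sp <- compute_speed(tf, 1, 10)
  bs <- classify_behavior(tf, frame_rate = 10)
  times <- seq(120, cfg$duration - 120, by = 60)
  rate <- compute_turn_rate(bs$events, times, window = 240)
  spd <- vapply(times, function(t0)
    mean(sp[abs(tf$time - t0) < 120], na.rm = TRUE), numeric(1))
  expect_gt(series_correlation(spd, rate), 0)
})
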