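# Distribution-level statistics: Sarle's bimodality coefficient, the
# intra-/inter-animal variability decomposition, and simple two-sample
# helpers.

#' Sarle's bimodality coefficient
#'
#' `BC = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))` with the
#' bias-corrected sample skewness `g1` and excess kurtosis `g2` (the
#' SAS/Sarle convention). Under this convention the uniform distribution
#' gives the critical value `BC_crit = 5/9` and a Gaussian gives 1/3;
#' values above 5/9 indicate possible bimodality. BC is invariant under
#' affine transforms of the sample.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @return object of class `bimodality_result`: list with `bc`,
#'   `skewness`, `excess_kurtosis`, `n`, `bc_crit` (5/9) and
#'   `is_bimodal` (`bc > 5/9`).
#' @examples
#' bimodality_coefficient(runif(1000))$bc   # ~ 5/9
#' bimodality_coefficient(rnorm(1000))$bc   # ~ 1/3
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 finite observations", call. = FALSE)
  if (var(x) == 0) stop("sample has zero variance", call. = FALSE)
  g1 <- e1071::skewness(x, type = 2)
  g2 <- e1071::kurtosis(x, type = 2)
  bc <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  structure(list(bc = bc, skewness = g1, excess_kurtosis = g2, n = n,
                 bc_crit = 5 / 9, is_bimodal = bc > 5 / 9),
            class = "bimodality_result")
}

#' Intra- vs inter-animal variability decomposition
#'
#' Separates within-individual from between-individual variability in a
#' matrix of repeated observations (animals x time points):
#' per-animal kernel densities, their average (the mean-of-intra
#' density), and the density of the per-timepoint population means. High
#' intra-animal variability yields a mean-of-intra density that
#' resembles the population density; high inter-animal variability (e.g.
#' clustered personal means) makes the mean-of-intra density multimodal
#' even though each animal stays unimodal — two regimes that are
#' indistinguishable at the population level.
#'
#' @param obs numeric matrix, one row per animal, one column per
#'   observation (time point).
#' @param grid_n evaluation grid size.
#' @param bw_floor minimum kernel bandwidth (guards degenerate animals);
#'   bandwidths follow Silverman's rule otherwise.
#' @return object of class `variability_decomposition`: list with
#'   `grid`, `per_animal` (matrix of densities, one row per animal),
#'   `mean_intra`, `population`, `intra_sd` (mean of per-animal SDs),
#'   `inter_sd` (SD of per-animal means), `animal_means`,
#'   `timepoint_means`.
#' @export
intra_inter_decomposition <- function(obs, grid_n = 512,
                                      bw_floor = 1e-3) {
  stopifnot(is.matrix(obs), nrow(obs) >= 2, ncol(obs) >= 2)
  tp_means <- colMeans(obs)
  lo <- min(obs, tp_means); hi <- max(obs, tp_means)
  pad <- 0.15 * (hi - lo) + 3 * bw_floor
  grid <- seq(lo - pad, hi + pad, length.out = grid_n)
  dens_of <- function(v) {
    bw <- max(bw.nrd0(v), bw_floor)
    density(v, bw = bw, from = grid[1], to = grid[grid_n],
            n = grid_n)$y
  }
  per_animal <- t(apply(obs, 1, dens_of))
  structure(list(grid = grid,
                 per_animal = per_animal,
                 mean_intra = colMeans(per_animal),
                 population = dens_of(tp_means),
                 intra_sd = mean(apply(obs, 1, sd)),
                 inter_sd = sd(rowMeans(obs)),
                 animal_means = rowMeans(obs),
                 timepoint_means = tp_means),
            class = "variability_decomposition")
}

#' L1 distance between two densities on a common grid
#'
#' @param d1,d2 density values on `grid`.
#' @param grid common evaluation grid.
#' @return integral of |d1 - d2| (0 for identical densities, up to 2).
#' @export
density_l1 <- function(d1, d2, grid) {
  sum(abs(d1 - d2) * c(diff(grid), 0))
}

#' Two-sample Student's t test with effect size
#'
#' Wraps [stats::t.test()] (pooled variance by default; Welch optional)
#' and adds Cohen's d.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param var_equal pooled-variance (classic Student) when TRUE.
#' @return list with `t`, `df`, `p_value`, `cohens_d`, `mean_a`,
#'   `mean_b`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- t.test(a, b, var.equal = var_equal)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  d <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, cohens_d = d,
       mean_a = mean(a), mean_b = mean(b))
}

#' Pearson correlation between two aligned series
#'
#' @param a,b numeric series of equal length; pairs with missing values
#'   are dropped.
#' @return Pearson r.
#' @export
series_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  cor(a[ok], b[ok])
}

#' Bootstrap comparison of bimodality coefficients over animals
#'
#' A t test on a single BC per condition is ill-posed, so the comparison
#' resamples animals with replacement within each condition, recomputes
#' the pooled-per-animal-mean BC for each replicate, and reports the
#' bootstrap distribution of the difference.
#'
#' @param obs_a,obs_b observation matrices (animals x observations).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `bc_a`, `bc_b`, `diff` (observed), `boot_diff`
#'   (replicates), `p_value` (two-sided bootstrap p for no difference).
#' @export
bc_bootstrap_test <- function(obs_a, obs_b, n_boot = 500, seed = 1) {
  set.seed(seed)
  bc_of <- function(m) bimodality_coefficient(rowMeans(m))$bc
  bc_a <- bc_of(obs_a); bc_b <- bc_of(obs_b)
  bd <- vapply(seq_len(n_boot), function(i) {
    ra <- obs_a[sample(nrow(obs_a), replace = TRUE), , drop = FALSE]
    rb <- obs_b[sample(nrow(obs_b), replace = TRUE), , drop = FALSE]
    tryCatch(bc_of(ra) - bc_of(rb), error = function(e) NA_real_)
  }, numeric(1))
  bd <- bd[is.finite(bd)]
  p <- 2 * min(mean(bd <= 0), mean(bd >= 0))
  list(bc_a = bc_a, bc_b = bc_b, diff = bc_a - bc_b, boot_diff = bd,
       p_value = min(1, p))
}

#' Plot a variability decomposition
#'
#' Per-animal densities (thin), their mean (thick), and the population
#' density, in the style used to contrast intra- and inter-animal
#' variability regimes.
#'
#' @param x a `variability_decomposition`.
#' @param ... passed to [plot()].
#' @export
plot.variability_decomposition <- function(x, ...) {
  ylim <- c(0, max(x$per_animal, x$mean_intra, x$population))
  plot(x$grid, x$population, type = "l", col = "red", lwd = 2,
       xlab = "observation", ylab = "probability density", ylim = ylim,
       ...)
  for (i in seq_len(nrow(x$per_animal))) {
    lines(x$grid, x$per_animal[i, ], col = gray(0.6, 0.5))
  }
  lines(x$grid, x$mean_intra, col = "purple", lwd = 2)
  legend("topright", legend = c("population", "mean of intra",
                                "individual"),
         col = c("red", "purple", gray(0.6)), lwd = c(2, 2, 1),
         bty = "n")
  invisible(x)
}
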