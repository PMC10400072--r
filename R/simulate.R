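# Synthetic-larva simulator: run-and-turn trajectories, rendered videos and
# the Gaussian intra/inter-animal variability toy model.

#' Simulation configuration
#'
#' Parameters of the synthetic crawling-larva generator. Defaults emulate
#' the recording conditions the toolkit targets: a handful of second-instar
#' larvae (each imaged as a cluster of roughly 30 bright pixels) on a
#' 22 x 22 cm agar arena filmed at 10 Hz, with slow background drift,
#' occasional occlusion/relocation events (a robot arm briefly blocking the
#' camera and returning the animal to the arena centre) and rare pairwise
#' collisions.
#'
#' @param n_animals number of larvae.
#' @param arena_side arena side length (mm).
#' @param px_per_mm imaging scale (px/mm).
#' @param frame_rate imaging rate (Hz).
#' @param duration simulated duration (s).
#' @param mean_speed mean crawl speed during runs at t = 0 (mm/s).
#' @param speed_decay linear drift of mean speed (mm/s^2, usually <= 0).
#' @param turn_rate turn events per minute (overall event rate, including
#'   the paused turn blocks themselves).
#' @param turn_size_mean mean unsigned turn magnitude (degrees).
#' @param turn_size_dispersion SD of the unsigned turn magnitude (degrees).
#' @param turn_duration_mean mean duration of the paused turn block (s).
#' @param run_heading_sd per-frame heading diffusion during runs (degrees),
#'   giving gently curved run paths.
#' @param handedness_bias in [-1, 1]; probability of a left (counter-
#'   clockwise) turn is (1 + handedness_bias)/2.
#' @param gradient_bias >= 0; strength of the tilt of the post-turn heading
#'   distribution toward +x (the gradient axis). 0 disables it.
#' @param collision_rate pairwise collision events per hour (whole arena).
#' @param occlusion_rate occlusion/relocation events per hour per animal.
#' @param occlusion_duration duration of each occlusion (s).
#' @param larva_length,larva_width rendered body dimensions (mm).
#' @param intensity peak body intensity (0-255 scale).
#' @param background_level baseline background intensity.
#' @param noise_sd per-pixel additive Gaussian noise SD (intensity units).
#' @param background_drift background drift per frame (intensity units);
#'   applied as a smooth spatial pattern growing linearly in time.
#' @param rng_seed integer seed; the same seed and configuration give
#'   bit-identical trajectories and frames.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_animals = 2, duration = 30, rng_seed = 7)
#' truth <- simulate_trajectories(cfg)
#' head(truth$frames)
#' @export
sim_config <- function(n_animals = 6,
                       arena_side = 220,
                       px_per_mm = 4,
                       frame_rate = 10,
                       duration = 600,
                       mean_speed = 0.5,
                       speed_decay = 0,
                       turn_rate = 3,
                       turn_size_mean = 60,
                       turn_size_dispersion = 30,
                       turn_duration_mean = 2,
                       run_heading_sd = 3,
                       handedness_bias = 0,
                       gradient_bias = 0,
                       collision_rate = 0.63,
                       occlusion_rate = 0.87,
                       occlusion_duration = 4.5,
                       larva_length = 3,
                       larva_width = 0.75,
                       intensity = 200,
                       background_level = 12,
                       noise_sd = 2,
                       background_drift = 0.01,
                       rng_seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals), arena_side = arena_side,
    px_per_mm = px_per_mm, frame_rate = frame_rate, duration = duration,
    mean_speed = mean_speed, speed_decay = speed_decay,
    turn_rate = turn_rate, turn_size_mean = turn_size_mean,
    turn_size_dispersion = turn_size_dispersion,
    turn_duration_mean = turn_duration_mean,
    run_heading_sd = run_heading_sd,
    handedness_bias = handedness_bias, gradient_bias = gradient_bias,
    collision_rate = collision_rate, occlusion_rate = occlusion_rate,
    occlusion_duration = occlusion_duration,
    larva_length = larva_length, larva_width = larva_width,
    intensity = intensity, background_level = background_level,
    noise_sd = noise_sd, background_drift = background_drift,
    rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  stop_if_not_finite(num, "sim_config")
  nonneg <- c("turn_rate", "turn_size_dispersion", "turn_duration_mean",
              "collision_rate", "occlusion_rate", "occlusion_duration",
              "noise_sd", "background_drift", "gradient_bias",
              "run_heading_sd")
  for (f in nonneg) {
    if (cfg[[f]] < 0) stop(sprintf("'%s' must be non-negative", f),
                           call. = FALSE)
  }
  if (cfg$handedness_bias < -1 || cfg$handedness_bias > 1) {
    stop("'handedness_bias' must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$n_animals < 1) stop("'n_animals' must be >= 1", call. = FALSE)
  for (f in c("arena_side", "px_per_mm", "frame_rate", "duration",
              "mean_speed", "larva_length", "larva_width")) {
    if (cfg[[f]] <= 0) stop(sprintf("'%s' must be positive", f),
                            call. = FALSE)
  }
  if (cfg$intensity <= 0 || cfg$intensity > 255) {
    stop("'intensity' must lie in (0, 255]", call. = FALSE)
  }
  if (cfg$background_level < 0 || cfg$background_level > 100) {
    stop("'background_level' must lie in [0, 100]", call. = FALSE)
  }
  if (cfg$turn_rate > 0 &&
      60 / cfg$turn_rate - cfg$turn_duration_mean < 0.5) {
    stop("turn_rate too high for turn_duration_mean: mean run duration ",
         "would fall below 0.5 s", call. = FALSE)
  }
  invisible(cfg)
}

# Poisson event times on [0, duration] (s) at `rate` events per hour.
poisson_times <- function(rate_per_hour, duration) {
  if (rate_per_hour <= 0) return(numeric(0))
  n <- rpois(1, rate_per_hour * duration / 3600)
  sort(runif(n, 0, duration))
}

#' Simulate run-and-turn larva trajectories with ground truth
#'
#' A modified 2D random walk: larvae alternate forward runs (speed with an
#' optional linear drift, small per-frame heading diffusion) and paused
#' turns with a signed heading change. Turn direction is left with
#' probability (1 + handedness_bias)/2; turn magnitudes follow a truncated
#' normal. A positive `gradient_bias` tilts the post-turn heading
#' distribution toward +x by accept/reject reweighting with weight
#' exp(gradient_bias * (cos(heading) - 1)), a simple klinokinesis
#' surrogate that yields a controllable navigation index. Larvae reflect
#' off the arena edge. Occlusion/relocation events freeze the animal,
#' hide it for `occlusion_duration`, then teleport it near the arena
#' centre (the synthetic analogue of a robot pick-up); collision events
#' steer one animal into another and hold the pair overlapped briefly.
#'
#' @param config a [sim_config()].
#' @return an object of class `larva_truth`: a list with
#'   \describe{
#'     \item{frames}{data.frame, one row per frame per animal: `frame`,
#'       `time` (s), `id`, `x`, `y` (mm), `heading` (rad), `state`
#'       ("run"/"turn"), `speed` (mm/s), `visible`, `bend` (deg, signed),
#'       `head_x`, `head_y`, `tail_x`, `tail_y` (mm).}
#'     \item{turns}{turn log: `id`, `onset_frame`, `offset_frame`,
#'       `size_deg` (signed, positive = left).}
#'     \item{events}{occlusion/relocation and collision events with frame
#'       spans and before/after positions.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$rng_seed)
  fr <- cfg$frame_rate
  n_frames <- max(2L, as.integer(round(cfg$duration * fr)))
  n <- cfg$n_animals
  margin <- cfg$larva_length

  # per-run-frame turn hazard chosen so that the overall event rate
  # (runs + paused turn blocks) matches turn_rate events/min
  if (cfg$turn_rate > 0) {
    mean_run_s <- 60 / cfg$turn_rate - cfg$turn_duration_mean
    p_turn <- 1 / (mean_run_s * fr)
  } else {
    p_turn <- 0
  }
  run_sd <- deg2rad(cfg$run_heading_sd)

  # schedules
  occl_times <- lapply(seq_len(n), function(i)
    poisson_times(cfg$occlusion_rate, cfg$duration))
  coll_times <- if (n >= 2) poisson_times(cfg$collision_rate, cfg$duration)
                else numeric(0)

  # per-animal state; initial placement keeps animals well separated
  x <- runif(n, margin * 3, cfg$arena_side - margin * 3)
  y <- runif(n, margin * 3, cfg$arena_side - margin * 3)
  if (n >= 2) {
    for (try in 1:200) {
      d <- as.matrix(dist(cbind(x, y))); diag(d) <- Inf
      bad <- which(apply(d, 1, min) < 5 * cfg$larva_length)
      if (length(bad) == 0) break
      x[bad] <- runif(length(bad), margin * 3, cfg$arena_side - margin * 3)
      y[bad] <- runif(length(bad), margin * 3, cfg$arena_side - margin * 3)
    }
  }
  heading <- runif(n, -pi, pi)
  mode <- rep("run", n)
  left <- integer(n)          # frames remaining in the current block
  bend <- numeric(n)          # signed body bend, degrees
  dhead <- numeric(n)         # per-frame heading increment during a turn
  turn_sign <- numeric(n)
  turn_mag <- numeric(n)
  turn_onset <- integer(n)
  turn_len <- integer(n)
  no_turn_until <- integer(n) # frame before which new turns are suppressed
  occl_ptr <- rep(1L, n)
  pickup <- matrix(NA_real_, n, 2)
  occl_start <- integer(n)

  coll_ptr <- 1L
  ac <- NULL                  # active collision controller

  # output buffers
  X <- matrix(NA_real_, n_frames, n); Y <- X; H <- X; SP <- X; BD <- X
  ST <- matrix("run", n_frames, n); VIS <- matrix(TRUE, n_frames, n)
  turns <- list(); events <- list()

  draw_turn <- function(h) {
    # returns list(sign, mag_deg, new_heading); gradient bias applied by
    # accept/reject with weight exp(g * (cos(h') - 1)) <= 1
    for (try in 1:40) {
      s <- if (runif(1) < (1 + cfg$handedness_bias) / 2) 1 else -1
      mag <- abs(rnorm(1, cfg$turn_size_mean, cfg$turn_size_dispersion))
      mag <- min(max(mag, 10), 170)
      h2 <- h + s * deg2rad(mag)
      if (cfg$gradient_bias <= 0) break
      if (runif(1) < exp(cfg$gradient_bias * (cos(h2) - 1))) break
    }
    list(sign = s, mag = mag, new_heading = h2)
  }

  reflect <- function(i) {
    if (x[i] < margin) { x[i] <<- margin; heading[i] <<- wrap_angle(pi - heading[i]) }
    if (x[i] > cfg$arena_side - margin) { x[i] <<- cfg$arena_side - margin; heading[i] <<- wrap_angle(pi - heading[i]) }
    if (y[i] < margin) { y[i] <<- margin; heading[i] <<- wrap_angle(-heading[i]) }
    if (y[i] > cfg$arena_side - margin) { y[i] <<- cfg$arena_side - margin; heading[i] <<- wrap_angle(-heading[i]) }
  }

  for (t in seq_len(n_frames)) {
    tsec <- (t - 1) / fr

    # start a collision event when scheduled and none is active
    if (is.null(ac) && coll_ptr <= length(coll_times) &&
        tsec >= coll_times[coll_ptr]) {
      coll_ptr <- coll_ptr + 1L
      cand <- which(mode == "run")
      if (length(cand) >= 2) {
        # closest eligible pair: seeker b, target a
        dmat <- as.matrix(dist(cbind(x[cand], y[cand])))
        diag(dmat) <- Inf
        ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        a <- cand[ij[1]]; b <- cand[ij[2]]
        ac <- list(a = a, b = b, phase = "seek", left = 0L,
                   deadline = t + as.integer(20 * fr), start = NA_integer_)
        mode[b] <- "seek"
      }
    }

    # collision controller
    if (!is.null(ac)) {
      a <- ac$a; b <- ac$b
      if (ac$phase == "seek") {
        if (mode[a] != "run" || t > ac$deadline) {
          mode[b] <- "run"; ac <- NULL            # abort
        } else {
          heading[b] <- atan2(y[a] - y[b], x[a] - x[b])
          v <- 2 * max(cfg$mean_speed + cfg$speed_decay * tsec, 0.05)
          x[b] <- x[b] + v / fr * cos(heading[b])
          y[b] <- y[b] + v / fr * sin(heading[b])
          if (sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2) <
              0.45 * cfg$larva_length) {
            ang <- runif(1, -pi, pi)
            x[b] <- x[a] + 0.3 * cfg$larva_length * cos(ang)
            y[b] <- y[a] + 0.3 * cfg$larva_length * sin(ang)
            mode[a] <- "held"; mode[b] <- "held"
            ac$phase <- "hold"; ac$left <- as.integer(round(0.8 * fr))
            ac$start <- t
          }
        }
      } else if (ac$phase == "hold") {
        ac$left <- ac$left - 1L
        if (ac$left <= 0L) {
          heading[b] <- wrap_angle(heading[a] +
                                     runif(1, deg2rad(120), deg2rad(240)))
          mode[a] <- "run"; mode[b] <- "run"
          no_turn_until[c(a, b)] <- t + as.integer(2 * fr)
          events[[length(events) + 1]] <- data.frame(
            type = "collision", id = a, id2 = b,
            start_frame = ac$start, end_frame = t,
            x_before = NA_real_, y_before = NA_real_,
            x_after = NA_real_, y_after = NA_real_)
          ac <- NULL
        }
      }
    }

    for (i in seq_len(n)) {
      m <- mode[i]
      if (m == "seek" || m == "held") {
        # handled by the controller; bend relaxes
        bend[i] <- bend[i] * 0.5
      } else if (m == "occluded") {
        left[i] <- left[i] - 1L
        if (left[i] <= 0L) {
          nx <- cfg$arena_side / 2 + rnorm(1, 0, 3)
          ny <- cfg$arena_side / 2 + rnorm(1, 0, 3)
          events[[length(events) + 1]] <- data.frame(
            type = "relocation", id = i, id2 = NA_integer_,
            start_frame = occl_start[i], end_frame = t,
            x_before = pickup[i, 1], y_before = pickup[i, 2],
            x_after = nx, y_after = ny)
          x[i] <- nx; y[i] <- ny
          heading[i] <- runif(1, -pi, pi)
          mode[i] <- "run"; bend[i] <- 0
        }
      } else if (m == "turn") {
        k <- turn_len[i] - left[i] + 1L
        heading[i] <- wrap_angle(heading[i] + dhead[i])
        # head casts are wide even when the net heading change is small,
        # so the peak bend has a floor well above typical run wobble
        bend[i] <- turn_sign[i] *
          max(40, 0.8 * min(turn_mag[i], 120)) *
          sin(pi * k / (turn_len[i] + 1))
        left[i] <- left[i] - 1L
        if (left[i] <= 0L) {
          turns[[length(turns) + 1]] <- data.frame(
            id = i, onset_frame = turn_onset[i], offset_frame = t,
            size_deg = turn_sign[i] * turn_mag[i])
          mode[i] <- "run"
        }
      } else { # run
        oi <- occl_ptr[i]
        if (oi <= length(occl_times[[i]]) && tsec >= occl_times[[i]][oi] &&
            is.null(ac)) {
          occl_ptr[i] <- oi + 1L
          pickup[i, ] <- c(x[i], y[i])
          occl_start[i] <- t
          mode[i] <- "occluded"
          left[i] <- max(1L, as.integer(round(cfg$occlusion_duration * fr)))
        } else if (p_turn > 0 && t >= no_turn_until[i] &&
                   runif(1) < p_turn *
                     max(cfg$mean_speed + cfg$speed_decay * tsec, 0.02) /
                     cfg$mean_speed) {
          # the turn hazard shares the activity drift with crawl speed,
          # so a configured speed decay depresses both features together
          tw <- draw_turn(heading[i])
          turn_sign[i] <- tw$sign; turn_mag[i] <- tw$mag
          d <- max(2L, as.integer(round(
            rgamma(1, shape = 4, rate = 4 / cfg$turn_duration_mean) * fr)))
          turn_len[i] <- d; left[i] <- d
          dhead[i] <- (tw$new_heading - heading[i]) / d
          turn_onset[i] <- t
          mode[i] <- "turn"
        } else {
          heading[i] <- wrap_angle(heading[i] + rnorm(1, 0, run_sd))
          # mutual avoidance keeps animals apart unless a collision event
          # is deliberately steering this pair together
          in_coll <- !is.null(ac) && i %in% c(ac$a, ac$b)
          if (n >= 2 && !in_coll) {
            others <- setdiff(which(mode != "occluded"), i)
            if (length(others)) {
              dd <- sqrt((x[others] - x[i])^2 + (y[others] - y[i])^2)
              jmin <- which.min(dd)
              if (dd[jmin] < 2.5 * cfg$larva_length) {
                j <- others[jmin]
                heading[i] <- atan2(y[i] - y[j], x[i] - x[j])
              }
            }
          }
          v <- max(cfg$mean_speed + cfg$speed_decay * tsec, 0.02)
          x[i] <- x[i] + v / fr * cos(heading[i])
          y[i] <- y[i] + v / fr * sin(heading[i])
          reflect(i)
          bend[i] <- bend[i] * 0.5
        }
      }

      X[t, i] <- x[i]; Y[t, i] <- y[i]; H[t, i] <- heading[i]
      BD[t, i] <- bend[i]
      # the frame that completes a turn (mode already flipped back) and
      # the frame that starts one (mode just flipped forward) are both
      # turn frames
      in_turn <- m == "turn" || mode[i] == "turn"
      ST[t, i] <- if (in_turn) "turn" else "run"
      VIS[t, i] <- mode[i] != "occluded"
      SP[t, i] <- if (!in_turn && m == "run" && mode[i] == "run")
        max(cfg$mean_speed + cfg$speed_decay * tsec, 0.02) else 0
    }
  }

  hl <- cfg$larva_length / 2
  br <- deg2rad(BD)
  frames <- data.frame(
    frame = rep(seq_len(n_frames), n),
    time = rep((seq_len(n_frames) - 1) / fr, n),
    id = rep(seq_len(n), each = n_frames),
    x = as.vector(X), y = as.vector(Y), heading = as.vector(H),
    state = as.vector(ST), speed = as.vector(SP),
    visible = as.vector(VIS), bend = as.vector(BD),
    head_x = as.vector(X + hl * cos(H + br / 2)),
    head_y = as.vector(Y + hl * sin(H + br / 2)),
    tail_x = as.vector(X - hl * cos(H - br / 2)),
    tail_y = as.vector(Y - hl * sin(H - br / 2)))
  out <- list(
    frames = frames,
    turns = if (length(turns)) do.call(rbind, turns) else
      data.frame(id = integer(0), onset_frame = integer(0),
                 offset_frame = integer(0), size_deg = numeric(0)),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(type = character(0), id = integer(0), id2 = integer(0),
                 start_frame = integer(0), end_frame = integer(0),
                 x_before = numeric(0), y_before = numeric(0),
                 x_after = numeric(0), y_after = numeric(0)),
    config = cfg)
  class(out) <- "larva_truth"
  out
}

#' Simulate a scripted two-animal crossing
#'
#' Deterministic benchmark scenario for collision resolution: two larvae
#' crawl along straight paths that intersect at the arena centre at the
#' same time, with a configurable crossing angle. No turns, occlusions or
#' heading diffusion.
#'
#' @param config a [sim_config()] (use a small arena, e.g. 40 mm).
#' @param angle crossing angle between the two paths (degrees).
#' @param seed optional seed overriding `config$rng_seed` (perturbs start
#'   phases slightly so repeated crossings differ).
#' @return a `larva_truth` object with two animals.
#' @export
simulate_crossing <- function(config, angle = 90, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(if (is.null(seed)) cfg$rng_seed else as.integer(seed))
  fr <- cfg$frame_rate
  n_frames <- max(2L, as.integer(round(cfg$duration * fr)))
  cx <- cfg$arena_side / 2
  v <- cfg$mean_speed
  half_path <- v * (n_frames / 2) / fr
  a1 <- runif(1, -pi, pi)
  a2 <- a1 + deg2rad(angle) * sample(c(-1, 1), 1)
  # small timing offset so the crossing is near, not exactly at, the centre
  dt_off <- runif(1, -0.5, 0.5)
  tt <- (seq_len(n_frames) - 1) / fr
  mk <- function(a, off) {
    s <- v * (tt - n_frames / 2 / fr - off)
    cbind(cx + s * cos(a), cx + s * sin(a))
  }
  p1 <- mk(a1, 0); p2 <- mk(a2, dt_off)
  frames <- data.frame(
    frame = rep(seq_len(n_frames), 2), time = rep(tt, 2),
    id = rep(1:2, each = n_frames),
    x = c(p1[, 1], p2[, 1]), y = c(p1[, 2], p2[, 2]),
    heading = rep(c(a1, a2), each = n_frames),
    state = "run", speed = v, visible = TRUE, bend = 0,
    head_x = c(p1[, 1], p2[, 1]) +
      cfg$larva_length / 2 * rep(c(cos(a1), cos(a2)), each = n_frames),
    head_y = c(p1[, 2], p2[, 2]) +
      cfg$larva_length / 2 * rep(c(sin(a1), sin(a2)), each = n_frames),
    tail_x = c(p1[, 1], p2[, 1]) -
      cfg$larva_length / 2 * rep(c(cos(a1), cos(a2)), each = n_frames),
    tail_y = c(p1[, 2], p2[, 2]) -
      cfg$larva_length / 2 * rep(c(sin(a1), sin(a2)), each = n_frames))
  out <- list(frames = frames,
              turns = data.frame(id = integer(0), onset_frame = integer(0),
                                 offset_frame = integer(0),
                                 size_deg = numeric(0)),
              events = data.frame(),
              config = cfg)
  class(out) <- "larva_truth"
  out
}

#' Gaussian intra/inter-animal variability model
#'
#' Toy generative model for the variability decomposition: animal i draws
#' a personal mean mu_i ~ Normal(mu_population, sigma_inter^2) (or from
#' explicitly placed cluster centres) and then emits observations
#' ~ Normal(mu_i, sigma_intra^2).
#'
#' @param n_animals number of animals (>= 2).
#' @param n_obs_per_animal observations per animal (>= 2).
#' @param mu_population population mean.
#' @param sigma_intra within-animal SD (>= 0).
#' @param sigma_inter between-animal SD (>= 0).
#' @param cluster_centers optional vector of cluster centres; when given,
#'   animals are assigned to centres in round-robin order and mu_i is drawn
#'   around the assigned centre with SD `sigma_inter` (models discrete
#'   behavioural phenotypes).
#' @param rng_seed integer seed.
#' @return object of class `variability_model`.
#' @export
variability_model <- function(n_animals, n_obs_per_animal,
                              mu_population = 0, sigma_intra = 1,
                              sigma_inter = 1, cluster_centers = NULL,
                              rng_seed = 1L) {
  stopifnot(n_animals >= 2, n_obs_per_animal >= 2,
            sigma_intra >= 0, sigma_inter >= 0)
  structure(list(n_animals = as.integer(n_animals),
                 n_obs_per_animal = as.integer(n_obs_per_animal),
                 mu_population = mu_population,
                 sigma_intra = sigma_intra, sigma_inter = sigma_inter,
                 cluster_centers = cluster_centers,
                 rng_seed = as.integer(rng_seed)),
            class = "variability_model")
}

#' Sample the variability model
#'
#' @param model a [variability_model()].
#' @return list with `observations` (matrix, animals x observations),
#'   `mu` (the drawn per-animal means) and `model`.
#' @export
simulate_variability <- function(model) {
  stopifnot(inherits(model, "variability_model"))
  set.seed(model$rng_seed)
  n <- model$n_animals
  if (is.null(model$cluster_centers)) {
    mu <- rnorm(n, model$mu_population, model$sigma_inter)
  } else {
    centers <- rep(model$cluster_centers, length.out = n)
    mu <- rnorm(n, centers, model$sigma_inter)
  }
  obs <- matrix(rnorm(n * model$n_obs_per_animal, mean = mu,
                      sd = model$sigma_intra),
                nrow = n, ncol = model$n_obs_per_animal)
  list(observations = obs, mu = mu, model = model)
}
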