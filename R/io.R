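# Configuration files, tabular readers/writers, manifests and the
# programmatic entry points behind the command-line interface.

pipeline_sections <- c("sim", "tracker", "linking", "behavior",
                       "features", "seed", "output_dir")

#' Read a pipeline configuration file
#'
#' YAML with sections `sim` (see [sim_config()]), `tracker` (see
#' [track_config()]), `linking` (see [linking_config()]), `behavior`,
#' `features`, plus `seed` and `output_dir`. Unknown sections or unknown
#' keys within a section are rejected, so configurations round-trip
#' losslessly and typos fail loudly.
#'
#' @param path YAML file path.
#' @return object of class `pipeline_config`: list with validated
#'   `sim` (`sim_config`), `tracker` (`track_config`), `behavior`,
#'   `features`, `seed`, `output_dir` and the raw list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_sections)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in '%s': %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  sim_args <- raw$sim %||% list()
  check_keys(sim_args, names(formals(sim_config)), "sim")
  if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- seed
  sim <- do.call(sim_config, sim_args)
  lk_args <- raw$linking %||% list()
  check_keys(lk_args, names(formals(linking_config)), "linking")
  lk <- do.call(linking_config, lk_args)
  tr_args <- raw$tracker %||% list()
  check_keys(tr_args, setdiff(names(formals(track_config)), "linking"),
             "tracker")
  tr_args$linking <- lk
  if (is.null(tr_args$px_per_mm)) tr_args$px_per_mm <- sim$px_per_mm
  tracker <- do.call(track_config, tr_args)
  check_keys(raw$behavior, c("bend_threshold", "speed_threshold",
                             "min_block", "switching_cost"), "behavior")
  check_keys(raw$features, c("speed_window", "nav_window",
                             "gradient_axis", "turn_rate_window"),
             "features")
  structure(list(sim = sim, tracker = tracker,
                 behavior = raw$behavior, features = raw$features,
                 seed = seed,
                 output_dir = raw$output_dir, raw = raw),
            class = "pipeline_config")
}

#' Write a pipeline configuration file
#'
#' @param config a `pipeline_config` (or a plain list with the same
#'   sections).
#' @param path output YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- if (inherits(config, "pipeline_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

output_manifest <- function(out_dir, config_path, seed, inputs = list()) {
  manifest <- list(
    tool = "larvatrack",
    version = as.character(packageVersion("larvatrack")),
    seed = seed,
    config_hash = unname(tools::md5sum(config_path)),
    input_hashes = lapply(inputs, function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write ground truth to tabular files
#'
#' @param truth a `larva_truth`.
#' @param dir output directory.
#' @return invisibly, the paths written (`truth_frames.csv`,
#'   `truth_turns.csv`, `truth_events.csv`).
#' @export
write_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("truth_frames.csv", "truth_turns.csv",
                            "truth_events.csv"))
  write.csv(truth$frames, paths[1], row.names = FALSE)
  write.csv(truth$turns, paths[2], row.names = FALSE)
  write.csv(truth$events, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write tracking results to tabular files
#'
#' @param tracked a `larva_tracks` from [track_video()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_tracks <- function(tracked, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("tracks.csv", "events.csv"))
  write.csv(tracked$tracks, paths[1], row.names = FALSE)
  write.csv(tracked$events, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Read a track table written by [write_tracks()]
#' @param path `tracks.csv` path.
#' @return data.frame of per-frame per-animal rows.
#' @export
read_tracks <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate: configuration file to video + ground truth on disk
#'
#' @param config_path pipeline YAML (section `sim`).
#' @param out_dir output directory; receives `frames/` (PNG stack),
#'   truth tables and `manifest.json`.
#' @param write_video write the rendered PNG stack (can be slow for long
#'   simulations; the truth tables are always written).
#' @return invisibly, the `larva_truth`.
#' @export
cli_simulate <- function(config_path, out_dir, write_video = TRUE) {
  cfg <- read_pipeline_config(config_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- simulate_trajectories(cfg$sim)
  write_truth(truth, out_dir)
  if (write_video) {
    src <- render_video(truth)
    write_frames(src, file.path(out_dir, "frames"))
  }
  output_manifest(out_dir, config_path, cfg$seed)
  invisible(truth)
}

#' Track: video to identity-preserved track tables
#'
#' @param video_dir PNG image-stack directory (see [read_frames()]).
#' @param config_path pipeline YAML.
#' @param out_dir output directory.
#' @return invisibly, the `larva_tracks`.
#' @export
cli_track <- function(video_dir, config_path, out_dir) {
  cfg <- read_pipeline_config(config_path)
  src <- read_frames(video_dir, frame_rate = cfg$sim$frame_rate)
  tracked <- track_video(src, cfg$tracker)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tracks(tracked, out_dir)
  output_manifest(out_dir, config_path, cfg$seed,
                  inputs = list(video_first_frame =
                                  list.files(video_dir, full.names = TRUE)[1]))
  invisible(tracked)
}

#' Analyze: track tables to features and statistics report
#'
#' Per animal: run/turn segmentation (when posture columns are present),
#' speed, turn rate, handedness and navigation index; population level:
#' the intra/inter variability decomposition and bimodality of the
#' per-animal navigation-index means.
#'
#' @param tracks_path `tracks.csv` path.
#' @param config_path pipeline YAML.
#' @param out_dir output directory; receives `features.csv`,
#'   `turn_events.csv` and `report.json`.
#' @return invisibly, the report list.
#' @export
cli_analyze <- function(tracks_path, config_path, out_dir) {
  cfg <- read_pipeline_config(config_path)
  tracks <- read_tracks(tracks_path)
  if (nrow(tracks) == 0) stop("empty track table", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fr <- cfg$sim$frame_rate
  bh <- cfg$behavior
  has_bend <- "bend" %in% names(tracks)
  if (!has_bend) {
    warning("no posture columns in track table; ",
            "turn-based features skipped")
  }
  feat_rows <- list(); turn_rows <- list(); nav <- list()
  for (id in sort(unique(tracks$id))) {
    tr <- tracks[tracks$id == id, ]
    if (nrow(tr) < 10) next
    sp <- compute_speed(tr, window = 1, frame_rate = fr)
    ni <- navigation_index(tr, frame_rate = fr)
    nav[[as.character(id)]] <- ni$overall
    hand <- NA_real_; n_turns <- NA_integer_
    if (has_bend) {
      bs <- classify_behavior(
        tr, frame_rate = fr,
        bend_threshold = bh$bend_threshold %||% 20,
        speed_threshold = bh$speed_threshold,
        min_block = bh$min_block %||% 3)
      hand <- turn_handedness(bs$events)$handedness
      n_turns <- nrow(bs$events)
      if (n_turns > 0) {
        ev <- bs$events; ev$id <- id
        turn_rows[[length(turn_rows) + 1]] <- ev
      }
    }
    feat_rows[[length(feat_rows) + 1]] <- data.frame(
      id = id, n_frames = nrow(tr),
      mean_speed = mean(sp, na.rm = TRUE),
      n_turns = n_turns, handedness = hand,
      navigation_index = ni$overall)
  }
  features <- do.call(rbind, feat_rows)
  write.csv(features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  if (length(turn_rows)) {
    write.csv(do.call(rbind, turn_rows),
              file.path(out_dir, "turn_events.csv"), row.names = FALSE)
  }
  nav_v <- unlist(nav)
  report <- list(n_animals = nrow(features),
                 navigation_index_mean = mean(nav_v, na.rm = TRUE),
                 navigation_index_sd = sd(nav_v, na.rm = TRUE))
  if (sum(is.finite(nav_v)) >= 4 && sd(nav_v, na.rm = TRUE) > 0) {
    bc <- bimodality_coefficient(nav_v[is.finite(nav_v)])
    report$bimodality <- list(bc = bc$bc, bc_crit = bc$bc_crit,
                              is_bimodal = bc$is_bimodal)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  output_manifest(out_dir, config_path, cfg$seed,
                  inputs = list(tracks = tracks_path))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
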