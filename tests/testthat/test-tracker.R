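# End-to-end tracking: identity preservation, completeness, gaps and
# relocations.

test_that("clean video is tracked with full identity preservation", {
  cfg <- clean_sim_config(n_animals = 3, duration = 40, seed = 31)
  tr <- simulate_trajectories(cfg)
  src <- render_video(tr)
  res <- track_video(src, track_config(px_per_mm = cfg$px_per_mm,
                                       n_animals = 3))
  m <- match_tracks_to_truth(res, tr)
  expect_equal(m$frame_accuracy, 1)
  expect_equal(length(unique(res$tracks$id)), 3L)
  # detection completeness once the first-frame imprint has washed out
  expect_true(all(res$det_counts[40:src$n_frames] == 3))
  # no id twice in a frame; open tracks never exceed the cap
  dup <- tapply(res$tracks$id, res$tracks$frame,
                function(ids) any(duplicated(ids)))
  expect_false(any(dup))
  expect_lte(max(tapply(res$tracks$id, res$tracks$frame, length)), 3)
})

test_that("tracking identical input twice is bit-identical", {
  cfg <- clean_sim_config(n_animals = 2, duration = 15, seed = 32)
  tr <- simulate_trajectories(cfg)
  src <- render_video(tr)
  tc <- track_config(px_per_mm = cfg$px_per_mm, n_animals = 2)
  r1 <- track_video(src, tc)
  r2 <- track_video(src, tc)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$events, r2$events)
})

test_that("a 4.5 s occlusion is bridged by interpolation within one
           body length", {
  # straight crawler; frames blanked for 45 frames mid-run
  cfg <- clean_sim_config(n_animals = 1, duration = 40, seed = 33,
                          turn_rate = 0, run_heading_sd = 0)
  tr <- simulate_trajectories(cfg)
  src <- render_video(tr)
  gap <- 150:194
  blank <- matrix(cfg$background_level, src$dim[1], src$dim[2])
  occl <- frame_source(function(t) if (t %in% gap) blank else src$get(t),
                       src$n_frames, src$dim, src$frame_rate)
  res <- track_video(occl, track_config(px_per_mm = cfg$px_per_mm,
                                        n_animals = 1))
  got <- res$tracks
  filled <- got[got$frame %in% gap, ]
  expect_equal(nrow(filled), length(gap))
  expect_true(all(filled$interpolated))
  truth_pos <- tr$frames[tr$frames$frame %in% gap, ]
  err <- sqrt((filled$x - truth_pos$x)^2 + (filled$y - truth_pos$y)^2)
  expect_lt(max(err), cfg$larva_length)
  # interpolated frames are excluded from turn detection downstream
  tf <- merge(got, data.frame(frame = gap, in_gap = TRUE), all.x = TRUE)
  tf$bend <- 90  # even an extreme bend must not create a turn in the gap
  bs <- classify_behavior(tf[tf$id == 1, ], frame_rate = 10,
                          bend_threshold = 20)
  in_gap_turn <- any(bs$events$onset_frame %in% gap[3:43])
  expect_false(in_gap_turn)
})

test_that("relocation jumps are logged and not interpolated", {
  cfg <- clean_sim_config(n_animals = 1, duration = 240, seed = 34,
                          occlusion_rate = 60, arena_side = 120)
  tr <- simulate_trajectories(cfg)
  reloc_true <- tr$events[tr$events$type == "relocation", ]
  expect_gt(nrow(reloc_true), 0)
  src <- render_video(tr)
  res <- track_video(src, track_config(px_per_mm = cfg$px_per_mm,
                                       n_animals = 1))
  reloc_got <- res$events[res$events$type == "relocation", ]
  expect_gte(nrow(reloc_got), 1)
  # the tracker's gap matches a true event and no frames inside any
  # relocation gap were interpolated
  for (k in seq_len(nrow(reloc_got))) {
    gapf <- (reloc_got$start_frame[k] + 1):(reloc_got$end_frame[k] - 1)
    expect_false(any(res$tracks$frame %in% gapf &
                     res$tracks$interpolated))
  }
})

test_that("posture columns are attached when requested", {
  cfg <- clean_sim_config(n_animals = 1, duration = 20, seed = 35,
                          turn_rate = 0)
  tr <- simulate_trajectories(cfg)
  src <- render_video(tr)
  res <- track_video(src, track_config(px_per_mm = cfg$px_per_mm,
                                       n_animals = 1, posture = TRUE))
  got <- res$tracks
  expect_true(all(c("head_x", "tail_x", "mid_x", "bend",
                    "posture_conf") %in% names(got)))
  ok <- !is.na(got$head_x)
  expect_gt(mean(ok), 0.9)
  # head matches the true head (crawling head-first, no turns)
  tf <- tr$frames[match(got$frame[ok], tr$frames$frame), ]
  err_head <- sqrt((got$head_x[ok] - tf$head_x)^2 +
                   (got$head_y[ok] - tf$head_y)^2)
  err_tail <- sqrt((got$tail_x[ok] - tf$tail_x)^2 +
                   (got$tail_y[ok] - tf$tail_y)^2)
  expect_lt(median(err_head), 1)
  expect_lt(median(err_tail), 1)
  # no head/tail flips across the run
  flips <- sum(diff(err_head > err_tail + 1) != 0)
  expect_lte(flips, 2)
})
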