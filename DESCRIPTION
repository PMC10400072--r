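Package: larvatrack
Title: Multi-Larva Video Tracking and Behavioural Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting identity-preserved trajectories, postures
    and run/turn behavioural states from videos of crawling Drosophila
    larvae (dark background, bright animals, ~10 Hz), and for quantifying
    navigation from the resulting tracks. Includes an infinite-impulse-
    response dynamic background model, contour-based detection with size
    gating, greedy frame-to-frame identity linking with momentum-initialised
    collision resolution, contour-halving spine and body-bend estimation,
    run/turn segmentation with an explicit state-switching cost, trajectory
    features (speed, curvature, turn rate, turn handedness, navigation
    index, translation-only trajectory stitching), and distribution-level
    statistics (intra- vs inter-animal variability decomposition and
    Sarle's bimodality coefficient). A synthetic-larva simulator provides
    rendered videos with exhaustive ground truth so every stage of the
    pipeline can be validated without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
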