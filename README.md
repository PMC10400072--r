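# larvatrack

Tools for long-term behavioural quantification of crawling *Drosophila*
larvae from video: bright animals on a dark arena, imaged around 10 Hz,
over minutes to many hours. The package takes raw grayscale frames and
produces identity-preserved trajectories, head/tail/spine postures,
run/turn ethograms and navigation statistics — and it ships a
synthetic-larva simulator that renders videos with exhaustive ground
truth, so every stage of the pipeline is testable without recorded
animals.

## What it computes

**Position tracking.** Frames are contrast-enhanced by subtracting a
dynamic background maintained with an IIR filter,

&nbsp;&nbsp;&nbsp;&nbsp;*B*<sub>t</sub> = α *F*<sub>t</sub> + (1 − α) *B*<sub>t−1</sub>,

then larvae are detected as size-gated outermost contours. Identities
are linked frame to frame by greedily minimising the weighted loss

&nbsp;&nbsp;&nbsp;&nbsp;*L*<sub>ij</sub> = β<sub>r</sub> D(r<sub>i</sub>, r<sub>j</sub>) + β<sub>p</sub> D(p<sub>i</sub>, p<sub>j</sub>) + β<sub>a</sub> D(a<sub>i</sub>, a<sub>j</sub>)

over position, momentum and contour area (D = Euclidean distance).
Missed frames are bridged by flagged linear interpolation; large jumps
are logged as relocation events instead. When animals collide and their
contours merge, the pre-collision contours are translated — initialised
from momentum, refined for at most 50 epochs of overlap maximisation —
to keep identities through the merge.

**Posture.** Head and tail are located geometrically (curvature extrema
disambiguated by momentum) or by a recurrent U-Net heatmap network; the
spine is built by halving the contour at head and tail and taking
midpoints of equidistant pairs, giving the *midspine* position and the
body-bend angle.

**Behaviour.** Each frame is classified run/turn, by a deterministic
bend-and-speed heuristic or by a recurrent dense network (nine dense
layers with ReLU, bidirectional LSTM at the beginning and middle),
with an explicit cost for switching states. Turn events carry signed
sizes (left = positive).

**Features and statistics.** Crawl speed, trajectory curvature, turn
rate, turn handedness (N<sub>left</sub> − N<sub>right</sub>)/N<sub>total</sub>, the navigation index
⟨v<sub>x</sub>⟩/⟨v⟩ (+1 = straight up-gradient), translation-only trajectory
stitching across relocations, peri-event averages, Sarle's bimodality
coefficient with the BC<sub>crit</sub> = 5/9 criterion, and an
intra-/inter-animal variability decomposition that distinguishes
populations of similar individuals from populations of distinct
behavioural phenotypes with the same mean.

## Worked example

Simulate a small arena, render it, track it, and quantify one animal:

```r
library(larvatrack)

cfg <- sim_config(n_animals = 4, duration = 120, arena_side = 100,
                  turn_rate = 4, handedness_bias = 0.3,
                  collision_rate = 0, occlusion_rate = 0, rng_seed = 7)
truth  <- simulate_trajectories(cfg)
src    <- render_video(truth)
tracks <- track_video(src, track_config(px_per_mm = cfg$px_per_mm,
                                        n_animals = 4, posture = TRUE))

match_tracks_to_truth(tracks, truth)$frame_accuracy
#> [1] 1

one <- subset(tracks$tracks, id == 1)
bs  <- classify_behavior(one, frame_rate = 10)
nrow(bs$events)
#> [1] 3
turn_handedness(bs$events)$handedness
#> [1] 0.3333333
navigation_index(one, frame_rate = 10)$overall
#> [1] 0.33281
mean(compute_speed(one, window = 1, frame_rate = 10), na.rm = TRUE)
#> [1] 0.4545518
```

Every tracked frame of every simulated animal matched the correct
ground-truth identity (accuracy 1). Animal 1 made 3 turns in two
minutes (2 left, 1 right → handedness 0.33), crawled at ~0.45 mm/s, and
drifted up-gradient by chance (navigation index 0.33; short tracks are
noisy — the index of a straight up-gradient crawl is exactly +1, and a
long unbiased walk gives ≈ 0).

The bimodality coefficient hits its analytic landmark on a large
uniform sample:

```r
set.seed(1)
bimodality_coefficient(runif(1e5))$bc
#> [1] 0.5571484   # critical value 5/9 = 0.5555...
```

A command-line interface wraps the same functions
(`inst/cli/larvatrack simulate|track|analyze`, YAML configuration, PNG
image stacks as the lossless video format).

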