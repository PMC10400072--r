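---
title: "Tracking and quantifying crawling larvae: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and quantifying crawling larvae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

# Overview

`larvatrack` turns grayscale videos of crawling *Drosophila* larvae —
bright animals on a dark agar arena, imaged at about 10 Hz — into
identity-preserved trajectories, postures, run/turn ethograms and
navigation statistics. This vignette explains the models behind each
stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

# Position tracking

## Dynamic background

Arena appearance drifts over hours (condensation, dust, substrate
ageing), so a static background is not usable for long recordings. The
background is an exponentially weighted running average,

$$B_t = \alpha F_t + (1-\alpha) B_{t-1},$$

an infinite-impulse-response filter with feedforward coefficient
$\alpha$. The update is a convex combination, so $B$ provably stays
within the intensity range of the frames. The default $\alpha = 0.01$
at 10 Hz gives a time constant of roughly 10 s: slow enough that a
crawling larva (well under 1 mm/s) never becomes part of the
background, fast enough to absorb environmental drift. $B_0$ is the
first frame by default — the animals' initial imprint washes out with
the filter within a few tens of frames, which is why trackers allow a
short burn-in — with a median-of-first-N alternative in the
configuration.

## Detection

Foreground pixels are those with residual $F - B$ above a fixed
intensity threshold (default 40 on a 0–255 scale). A global fixed
offset, rather than adaptive thresholding, is deliberate: the animals
are uniformly bright on black, and a global threshold is exactly
reproducible. Holes are filled so only outermost contours count, and
connected components outside a pixel-area gate (default [10, 45] px²
for a single animal at 4 px/mm) are discarded. Centroids are mask-pixel
means; coordinates are half-open pixel indices with x rightward and y
downward, converted to mm (origin bottom-left, y up) for all behaviour
analysis.

## Identity linking

A detection $i$ is scored against a track $j$ with

$$L_{ij} = \beta_r D(r_i, r_j) + \beta_p D(p_i, p_j) +
  \beta_a D(a_i, a_j),$$

where $r$ is position, $p$ momentum (mean displacement per frame over
the last 5 frames; the detection-side momentum is its candidate
displacement), $a$ contour area, and $D$ the Euclidean distance
(absolute difference for the scalar area). Defaults
$\beta_r = 1, \beta_p = 0.5, \beta_a = 0.01$ balance the three terms at
pixel scale. Assignment is *greedy*: lowest loss first, then the next
lowest among the remaining pairs. This is intentionally not the
globally optimal assignment — the test suite constructs a 2×2 case
where greedy and optimal disagree and asserts the greedy result — and
ties break deterministically (lower track id, then detection index).
Pairs above a loss gate stay unmatched.

Unmatched tracks persist for up to `interp_max_gap` frames. When a
track is re-acquired after a gap, the gap is filled by linear
interpolation and flagged, unless the jump exceeds `relocation_jump`
(20 mm default), in which case the gap is logged as a relocation event
(the robot-transport analogue) and deliberately *not* interpolated —
those frames would otherwise inject enormous spurious velocities.
Interpolated frames are excluded from turn detection and from velocity
averages. Linear interpolation is sufficient because a larva crawls
well below one body length per frame at 10 Hz.

## Collisions

When two or more tracks' predicted positions ($r + p$) fall inside one
detection whose area exceeds the single-animal maximum, the contours
have merged and a collision opens. Each participant's last
pre-collision mask is translated so that the union of translated masks
best matches the merged mask. The spec of the optimisation is open in
the source method, so the package uses: intersection-over-union as the
objective, integer hill-climbing over a ±2 px neighbourhood per epoch,
at most 50 epochs, initialised at each participant's momentum. Two
details proved load-bearing in testing:

* the initial translation is the *fractional* momentum — slow crawlers
  move ~0.2 px/frame, and rounding the init to integers erases the
  motion prior that carries identities through deep overlap;
* a small penalty (3×10⁻³ per px of deviation from the init) breaks the
  plateau degeneracy of two similar masks that overlap completely,
  where IoU alone cannot distinguish "pass through" from "bounce".

If the final overlap stays below an IoU floor of 0.3 the optimisation
is declared failed and positions fall back to momentum extrapolation,
flagged in the event log. On scripted two-animal crossings with
crossing angles spanning 30–150°, post-separation identity recovery is
about 88% — near-head-on passes of identically shaped blobs remain
genuinely ambiguous without appearance cues.

# Posture

The default posture path is fully deterministic. Body ends are the two
contour vertices of locally maximal discrete curvature separated by at
least a third of the perimeter; the head is the end aligned with
momentum (larvae crawl head-first), with the previous assignment kept
when momentum is unreliable (< 0.2 px/frame) and a low-confidence
carry-over for near-circular contours. The spine follows the
contour-halving construction: split the contour at head and tail into
the two body sides, resample both to `n_points` (default 11 — odd, so
a unique middle vertex exists) by arc-length interpolation, and take
midpoints of equidistant pairs. The middle spine vertex (*midspine*) is
a better position estimate than the centroid for a bending animal. The
body bend is the angle at the midspine between the tail-half direction
into it and the head-half direction out of it; 0° is straight, and the
sign is positive for a head bent to the animal's left in mm
coordinates (the image-coordinate sign is flipped on output because
image y points down).

A recurrent U-Net heatmap network is also provided: four encoder
submodules (3×3 convolution, ReLU, 2×2 max pooling), a mirrored
decoder with nearest-neighbour upsampling, skip connections, and
convolutional LSTM cells at the encoder input, bottleneck and decoder
output; the two output channels are spatial softmaxes over the crop
(head and tail probability maps), decoded by argmax with quadratic
subpixel refinement. The source method under-specifies channel counts
and kernel sizes, so this is an interpretation at deliberately small
scale (4 base channels), built on the package's own reverse-mode
autograd. Training uses per-frame cross-entropy against Gaussian
target maps (σ = 1.5 px) with the recurrent state reset per sample;
the suite verifies that a short training run reduces keypoint error on
synthetic crops. Matching a production-trained network's accuracy on
real video is a non-goal; the geometric estimator is the pipeline
default so results are reproducible without training.

# Behaviour

The default classifier is a deterministic heuristic: a frame is a turn
candidate when |body bend| > 20° *and* speed < 40% of the animal's
median positive speed; blocks shorter than 3 frames (at 10 Hz) are
merged into their neighbours, which implements the "cost for switching
behavioural states" deterministically and guarantees strict run/turn
alternation. Turn size is the wrapped difference of local run headings
after vs before the block (headings from displacement over ±5 frames);
positive = left = counter-clockwise in mm coordinates. Events too
close to the series edge get an ambiguous direction and are excluded
from handedness counts (but reported).

The network alternative is a sequence of nine dense linear layers
alternating with ReLU and a bidirectional LSTM at the beginning and
middle (11 layers), softmax over states, trained with a 10-fold loss
weight on turn frames since runs dominate. At inference the
per-frame probabilities are decoded by a two-state dynamic program
with a per-transition log-penalty — the explicit switching cost. The
penalty's position at inference (not training) time was an open
choice; the dynamic program makes the "infinite cost ⇒ single state"
limit and the monotone transitions-vs-cost property exactly testable.
Hidden width (16) and the thresholds above are configuration, not
constants of the method.

# Features and statistics

* **Speed** — central difference over a 1 s window (default), anchors
  never on interpolated frames.
* **Curvature** — the path is resampled at a fixed arc step; curvature
  is wrapped heading change per arc length, signed like turns.
* **Turn handedness** — $(N_{left} - N_{right})/N_{total}$; +1 all
  left, −1 all right; ambiguous turns excluded from the counts.
* **Navigation index** — $\langle v_x\rangle/\langle v\rangle$ with
  the denominator the mean of speed norms (not the norm of the mean
  velocity), so the index lies in $[-1, 1]$ by Cauchy–Schwarz; +1 is
  straight up-gradient. Interpolated and collision frames are excluded;
  windows with no net motion are flagged undefined.
* **Stitching** — each post-relocation segment is translated (never
  rotated, so headings and the gradient axis are preserved) to join the
  previous segment's end; cumulative length is reported in metres.
* **Peri-event averages** — event-aligned means ± SD with edge events
  dropped.

**Bimodality.** The bimodality coefficient uses the SAS/Sarle
finite-sample form
$BC = (g_1^2 + 1)\,/\,(g_2 + 3(n-1)^2/((n-2)(n-3)))$ with
bias-corrected skewness and excess kurtosis, because that is the
convention under which the critical value $BC_{crit} = 5/9$ (the
uniform-distribution value) holds; a Gaussian gives 1/3. The suite
verifies both landmarks on large fixed-seed samples.

**Intra vs inter-animal variability.** The generative toy model draws a
personal mean $\mu_i \sim \mathcal N(\mu, \sigma_{inter}^2)$ (or
around explicit cluster centres, modelling discrete behavioural
phenotypes) and observations $\sim \mathcal N(\mu_i,
\sigma_{intra}^2)$. The decomposition reports per-animal kernel
densities (Silverman bandwidth with a floor for degenerate animals),
their average (mean-of-intra), and the density of per-timepoint
cross-animal means. One subtlety: the per-timepoint-mean density is
narrower than any individual density by $\sqrt{n_{animals}}$ even with
zero inter-animal spread, so "agreement" between the regimes is
assessed against the pooled-observation density; the per-timepoint-mean
density is still computed and returned. The regime switch the package
demonstrates: with $\sigma_{inter} = 0$ the pooled per-animal-mean BC
stays ≤ 5/9 and the densities agree (L1 < 0.1); with two-cluster
personal means the pooled BC crosses 5/9 while every individual
sample stays unimodal. Because a t test on one BC per condition is
ill-posed, BC comparisons are exposed as a bootstrap over animals.

# The synthetic-larva simulator

The generator emulates the target recordings: 4–6 larvae on a
22 cm × 22 cm arena at 10 Hz, each rendered as an elongated soft-edged
blob of ~30 bright pixels (3 mm × 0.75 mm at 4 px/mm) with a mild
head-side width asymmetry, slow smooth background drift, optional
per-pixel Gaussian noise, occlusion/relocation events (a dark disc
covers the pick-up site for 4.5 s, then the animal reappears near the
arena centre — the robot-transport analogue, at 0.87 events/h/animal)
and pairwise collisions (0.63 events/h at six animals, steered
encounters held overlapped briefly).

Trajectories are a run-and-turn random walk: runs at a mean speed
(default 0.5 mm/s) with optional linear drift and small von-Mises-like
heading diffusion (3°/frame), turns as pauses with a signed heading
change — left with probability $(1 + h)/2$ for handedness bias $h$,
magnitude from a truncated normal (60° ± 30°; the source method states
no distributional form, so these are package defaults, stated once and
not tuned). During a turn the body bends with a sinusoidal cast profile
whose peak is the larger of 40° and 0.8× the turn magnitude: larvae
sweep their head widely even when the resulting net heading change is
small, and a bend-threshold classifier sees the cast, not the net
change. A gradient bias $g \ge 0$ tilts post-turn headings toward
+x by accept/reject with weight $e^{g(\cos\theta' - 1)}$ — the
simplest mechanism that produces a controllable navigation index. The
turn hazard is scaled by the instantaneous speed factor so a
configured speed decay depresses speed and turn rate together, which
is what long recordings of starving animals show. Run durations are
set so the overall event rate (including the paused blocks) matches
`turn_rate`; the suite checks this ergodically.

Two things the simulator deliberately does *not* emulate: peristaltic
body dynamics (blobs bend as two-segment chevrons — sufficient for
tracker and spine testing, not for gait analysis), and any thermal
physics (the gradient is a pure heading bias). With `collision_rate =
0` larvae actively avoid each other, so the clean regime is genuinely
collision-free and 100% identity preservation is a meaningful
requirement rather than a coin flip. Consequently, passing tests show
the pipeline recovers what this generative model produces; real video
adds appearance variation, illumination structure and contact
behaviours the model does not contain.

Reproducibility is strict: one integer seed makes trajectories and
frames bit-identical, and frame rendering derives a per-frame noise
seed so lazy random access is deterministic in any order.

# Problem sizes and numerical choices

The validation suite runs entirely on synthetic data generated at test
time: the identity-preservation benchmark uses six animals for 10
minutes at 10 Hz (6000 frames, 880×880 px); collision recovery uses 40
scripted crossings at 30–150°; parameter recovery uses 25–30 minute
trajectory-level simulations; distributional tests use 12–16 animals ×
400–600 observations. These sizes were chosen so each statistical
check sits several standard errors away from its threshold under the
generative model.

Degenerate inputs are handled explicitly: zero-variance samples and
n < 4 are rejected by the bimodality coefficient; constant series by
the correlation; head = tail splits by the spine; sub-3 px animals by
the renderer; empty masks, empty detection lists and empty track lists
are all legal no-ops. Angle arithmetic wraps to (−180°, 180°] with the
boundary mapped to +180°.

# Known limitations

* Identity through near-head-on collisions of identical-looking
  animals is information-limited; the resolver's ~88% on crossings is
  honest, not a ceiling artefact of the optimiser.
* The geometric head/tail estimator relies on momentum; an animal that
  backs up for many frames can hold a flipped assignment until it
  crawls forward again. The recurrent network path exists precisely to
  add temporal/appearance cues, but is provided at demonstration scale.
* The heuristic classifier needs posture (bend); tracks without
  posture columns fall back to run-only features, with a warning.
* No illumination correction or lens-distortion model; no appearance
  re-identification after track loss beyond the relocation logic.
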