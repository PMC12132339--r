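---
title: "Methods: behavioral-state and neural analysis of social-exclusion sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral-state and neural analysis of social-exclusion sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fomopipe` implements the analysis stack for a trial-structured social
"FOMO" paradigm: an excluded mouse, separated by a switchable barrier from
cagemates consuming reward, is exposed on every trial to a 10-s tone cue
and a 15-s transparent-wall window, with 40–60-s inter-trial intervals and
60 trials per session. The package covers the behavioral side (pose-derived
features, supervised attending detection, unsupervised state discovery) and
the neural side (calcium PSTHs and ensembles, population decoding,
trajectory geometry, biosensor photometry). Because the analyses are what
the package contributes, every stage is exercised on synthetic sessions
with planted ground truth rather than on recordings.

## Synthetic sessions

`sim_config()` fixes the study conditions: 60 trials, 10-s cue, 15-s wall,
ITI uniform on 40–60 s, a 245-s habituation delay, 30-fps video, 10-Hz
imaging, 20-Hz photometry. Where a quantity has no stated value we chose a
realistic one once: a 256-px overhead arena with the port across the
barrier; attending bouts generated by a sticky two-state process
(per-frame persistence 0.9) whose stationary occupancy is 0.7 inside
cue/wall windows and 0.05 outside; i.i.d. per-coordinate dropout (5%) to
exercise interpolation; keypoint jitter of 0.5 px. The generator's
attending truth is geometric — nose within 20 px of the barrier *and*
head-to-port angle below 45° — with placement margins that keep planted
frames clearly inside and other frames clearly outside the thresholds, so
the downstream feature extractor can be scored frame-for-frame against it.

Calcium sessions plant four response profiles (fast excited, sustained
excited, inhibited, flat) at each cue onset over unit-variance noise;
photometry plants cue-locked transients plus a smooth AR(1) motion
artifact shared between channels (reference gain configurable), slow
exponential bleach per channel, and small measurement noise. Every
generator draws from a seeded local RNG stream and restores the ambient
RNG, so identical configurations are byte-identical.

What the generators do *not* emulate: realistic biomechanics, occlusion
and identity swaps, non-Gaussian imaging noise, hemodynamic or
wavelength-specific photometry effects. Passing tests therefore certify
the *procedures* (windows, normalizations, selection rules, decoders), not
performance on real recordings.

## Behavioral features

Tracks are linearly interpolated over missing coordinates (edges held) and
smoothed with a centered moving mean (default 5 frames; the window is the
one free smoothing parameter). Features follow the standard definitions:
nose-to-port distance and unsigned head-to-port angle in [0, π]; torso
velocity/acceleration in px/s and px/s²; head-to-body and head-to-tail
orientation; turning angle between consecutive displacement vectors;
trailing 1-s and 5-s tortuosity (path length over net displacement);
nose-tail distance and its first difference; and the discrete zone (3
x-partitions of the excluded half), oriented-to-port, touching-barrier,
their conjunction, and huddle quality (constant 0 without cagemate tracks,
and excluded from z-scoring). Continuous features are z-scored over the
full session; discrete ones are never standardized.

Numerical choices: tortuosity of a stationary window is defined as 1; a
window that returns to its start (net displacement ≈ 0 with real path
length) is capped at 50 so standardization stays finite. Velocity of the
first frame copies the second. Freezing/dashing and reward-seeking
thresholds are configuration parameters with no canonical values.

## Attending detection

The detector regresses per-class heatmaps from single grayscale frames:
Gaussian targets (peak exactly 1 at each point label, overlaps combined by
max), a small stack of 3×3 stride-2 conv/ReLU blocks, nearest-neighbor
upsampling stages, and a 1×1 sigmoid head; training minimizes pixel-wise
BCE (positive pixels up-weighted 20×, MSE available) with Adam under a
seeded batch order. The default backbone is deliberately small so training
is CPU-feasible; widths, depths and the number of upsampling stages are
configurable up to a deeper encoder with three upsampling stages. Peaks
are read out by non-maximum suppression: strict 8-neighborhood local
maxima at or above the confidence threshold, greedily suppressed by
descending confidence (ties broken by row, then column) within an
inclusive Euclidean radius (defaults: confidence 0.5, radius 16 px at
input scale). A frame is positive when at least one detection survives.

Trial quantification subtracts the 5-s pre-cue baseline count from each of
the three 5-s post-cue bins and sums the three deltas. Median thresholds
label trials: global pools all animals and conditions, local pools one
animal across conditions; "more than the threshold" is read strictly, so
ties fall to not-attending. Extreme-trial selection takes the top 15 by
descending count (ties to the earlier trial) and the bottom 15 from the
remaining trials by ascending count — choosing the bottom set from the
remainder is what keeps the two sets disjoint under heavy ties.

## Behavioral state models

Trial-window features are embedded in 2-D and density-clustered. The
embedding backend is pluggable; the default is the first two principal
components with a deterministic sign convention, which keeps repeated runs
identical and satisfies the locality properties the downstream overlays
rely on (duplicated frames co-locate; well-separated feature blobs stay
separated). Clustering is DBSCAN with a grid-accelerated 2-D neighbor
search (eps defaults to 5% of the embedding span; minPts 10, counting the
point itself). Cluster annotation replicates the manual video-review step
via a user map, with a heuristic fallback (mean oriented-and-touching
above 0.5) for synthetic sessions.

The hidden-state model consumes one-hot syllable indicators (alphabet 87
by default) concatenated with five continuous and two discrete features.
Emissions are single full-covariance Gaussians per state — numerically
accepting the categorical block — fitted by EM with scaled
forward-backward recursions (compiled core), diagonal regularization 1e-6
(escalated tenfold on Cholesky failure, with a warning), relative
log-likelihood tolerance 1e-4, at most 500 iterations, and 5 restarts
(first k-means-seeded, the rest random). Because the raw training
log-likelihood is monotone in the state count, the 2–12 scan needs a
penalized criterion to be well-posed: the default is minimum BIC, with
maximum held-out log-likelihood on a 20% tail split as the alternative;
all per-K scores are retained on the returned model. State metrics report
time-in-state, mean dwell time, stickiness (empirical self-transition
probability), and the transition-count matrix both normalized over the
whole matrix and row-stochastically.

## Calcium analysis

PSTHs span −5 to +15 s at 10 Hz; each neuron-trial is z-scored as
(F(t) − Fm)/SD with both moments from the −1..0 s baseline, and
zero-variance baselines are flagged and excluded. Responsiveness uses the
paired Wilcoxon signed-rank test on per-trial 5-s baseline vs 5-s event
window means, at raw α = 0.05 (a Benjamini–Hochberg switch exists but is
off, matching the uncorrected convention); the sign of the mean z over
0–15 s labels significant neurons excited or inhibited. Ensembles are cut
from Ward linkage over correlation distance (1 − Pearson r between mean
profiles concatenated across conditions) at 30% of the maximum linkage
height; Ward formally presumes Euclidean geometry, and we keep the stated
combination deliberately. Overlap tables across event types are compared
with chi-squared tests.

Decoding fits the global PCA on training-fold trial averages only, keeps
the smallest component count reaching 90% cumulative variance, and trains
a per-timepoint linear classifier (L2-penalized logistic regression by
default, linear SVM as the alternative) under trial-level stratified
cross-validation (5-fold; 10-fold where trial counts allow) with balanced
subsampling of the majority class. Held-out decision values give the ROC
as a function of time and a window-averaged auROC per fold; the shuffled
control permutes training labels inside the same folds. Multi-class
problems use one-vs-all against trial-matched pools of the other classes,
repeated three times and averaged.

Trajectories project trial-averaged activity through fixed per-neuron PCA
coefficients, resample to 100 bins over −5..15 s, and measure geodesic
length as the sum of adjacent-bin Euclidean distances in the 90%-variance
subspace; between-trajectory distance is bin-by-bin. Leave-one-animal-out
replicates drop one animal's neurons per iteration while reusing the same
coefficients; a single-animal group is flagged as degenerate.

## Photometry

Both channels pass a forward-only (trailing) 200-ms median filter — the
"forward only" wording excludes centered windows. Regression coefficients
are ordinary least squares with intercept on the *trial-averaged* −1..0 s
baseline segments (reference → signal), which keeps evoked transients out
of the fit; the fitted reference projection is then subtracted over the
whole session, and each extracted trial (−5..+20 s) is z-transformed on
its own −1..0 s baseline. The residual itself (not a ΔF/F of it) is
z-scored, following the stated order of operations. Trial AUC is
trapezoidal over sensor-specific windows (0–20 s for dopamine and
oxytocin, 0–15 s for the endocannabinoid sensor). Random-forest decoding
pools (trial, timepoint) samples inside the window, splits folds at the
trial level so timepoints never leak, and reports one pooled ROC plus the
shuffled-training-label twin (500 trees by default; unstated in the
source, so configurable).

## Problem sizes and limitations

The test suite runs every stage on deliberately small sessions: 4–8 trials
for feature/detector fixtures, 250 training frames and ~15 epochs for the
detector, 3,000-frame sequences for HMM recovery checks, 500 null neurons
for the responsiveness calibration, and ten 10,000-frame sessions for the
state-count scan — sizes we consider sufficient to pin down each
procedure's behavior while keeping a full run to a few minutes.
Limitations worth knowing: the linear embedding backend separates
attending frames only weakly on realistic mixtures (a nonlinear embedding
would sharpen the clusters but adds a heavy dependency); the Gaussian
emission over one-hot syllable blocks is a numerical convenience, not a
generative truth; and HDF5 interfaces are not provided — all adapters are
plain-text CSV/JSON/YAML.
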