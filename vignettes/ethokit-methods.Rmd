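---
title: "Methods: behavioral kinematics of gap-jumping distance estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral kinematics of gap-jumping distance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethokit)
```

## The task and what the package measures

In the gap-jumping paradigm a mouse mounts a take-off platform, an occluder is
removed, and the animal must estimate the distance to a landing platform before
jumping. The interval from occluder removal to the last frame before the jump
(or an abort) is the *decision period*; everything this package quantifies is
computed on that window. The scientific questions the pipeline serves are how
head movements (a source of motion-parallax cues), head posture, eye movements,
and latent movement states differ between viewing conditions — typically
binocular versus monocular.

Inputs are markerless pose estimates (DeepLabCut-dialect CSV: per-frame x/y
pixel coordinates plus a tracking confidence per body part) from a side camera
and a top camera, optional head-mounted eye cameras tracking pupil points, and
a per-session trial table (condition, gap distance, platform width, outcome,
event frames). Frame indices are 0-based and the decision period is the
half-open interval `[start_frame, jump_frame)`.

## Preprocessing

Confidence filtering replaces samples below a threshold (default 0.9, standard
practice for DeepLabCut likelihoods) with gaps and linearly interpolates gaps
up to 100 ms; longer gaps stay missing rather than being fabricated.
Calibration converts pixels to centimetres and subtracts the
*session-median* position of the take-off-platform-edge landmark. The median,
not the per-frame position, is used because that landmark is physically static
and per-frame subtraction would inject tracker jitter into every other series.
The image vertical axis is flipped so +y is up; every angle convention below
follows from that single choice. Series are then smoothed with a running
median (n = 3 samples) followed by a box filter (n = 5 samples), both with
reflection padding so length is preserved and edges are not biased. Cameras at
other rates are resampled to 60 Hz by linear interpolation.

## Head kinematics

Pitch is the angle of the eye relative to the ear in the side view,
`atan2(eye_y - ear_y, eye_x - ear_x)` in degrees: 0° means the eye is level
with the ear and negative values mean downward head tilt. Yaw is the same
construction in the top view relative to the take-off-to-landing axis; summary
statistics use its magnitude while the signed series is retained. Distance
jumped is the horizontal position of the ear in the top view at the landing
frame, taken from raw (unsmoothed) calibrated positions so the estimate does
not depend on filter settings. Trial duration is sample count over rate, and
path length is the summed Euclidean step length of the smoothed eye
trajectory. Every summary statistic is averaged *within animal first, then
across animals*; with unequal trial counts per animal this is not the pooled
mean, and a unit test pins the distinction.

## Movement motifs

Discrete head movements are extracted from the smoothed decision-period eye
trajectory by five rules: (1) vertical velocity by central difference;
(2) velocity zero crossings, placed on whichever adjacent sample is nearer
zero velocity (runs of exact zeros yield one crossing at the run center —
a deterministic tie-break); (3) a 500 ms window around each crossing, with
crossings too close to the series edge dropped rather than padded; (4) windows
with vertical amplitude (max y − min y) under 1 cm discarded; (5) a
chronological scan discarding any movement that overlaps the last *retained*
movement by more than 250 ms. The vertical velocity component is used because
the amplitude criterion is vertical and the movements of interest are head
bobs; horizontal crossings are available via the `component` argument. The
implementation is checked against an independent plain-loop implementation of
the same five rules on 1,000 random traces.

Retained movements are flattened to concatenated `[x, y]` traces,
mean-centered, and embedded with PCA, keeping the smallest number of
components that reaches 95% cumulative variance (the retention level is
configurable). k-means (default k = 10, 20 restarts, best inertia, fixed
seed) clusters the scores, and clusters are relabeled in descending order of
total within-cluster trace variance so cluster 1 is always the most variable.
Per-cluster statistics (movements per trial, amplitude, normalized
time-before-jump histograms) follow the within-animal-first averaging rule.
The pitch-frequency relation across animals is summarized by a Spearman rank
correlation plus an ordinary least-squares line on per-animal
(Δpitch, Δfrequency) pairs.

## Gaze analysis

Pupil points from each eye camera are fit per frame with the numerically
stable direct least-squares ellipse fit (generalized eigenproblem on scatter
blocks constrained to `4AC − B² > 0`); the fit is exact on noiseless conics
and frames with fewer than five usable points are marked invalid. Eye-in-head
angles use a small spherical eye model: the pupil center displaces from its
rest position by `scale_px · sin(angle)`, so theta (horizontal, nasal
positive) and phi (vertical, up positive) are arcsines of normalized
displacement. The single `scale_px` per eye stands in for a full camera
calibration, which the pipeline deliberately does not model; it is exposed in
the configuration. Vergence is `theta_left + theta_right` under the
nasal-positive convention, so positive vergence means convergence (greater
binocular overlap). Decision periods are split into an early epoch (start to
2 s before the jump) and a late epoch (final 2 s); trials of 2 s or less get
an empty early epoch with a warning. Head-eye coupling is quantified by
normalized cross-correlation (Pearson at each integer lag over the overlap)
computed per trial and then averaged, and by ordinary least squares of the
gaze variable on pitch.

## Latent movement states

The state model is a sticky autoregressive hidden Markov model: given state
`k`, the observation follows `y_t = A_k y_{t-1} + b_k + ε`, `ε ~ N(0, Σ_k)`,
with a `K × K` transition matrix biased toward self-transitions by a
pseudo-count `kappa`. Features are the platform-edge-centered x/y positions of
the nose, eye, and ear (6-D), downsampled 2×. Fitting is by EM: a scaled
forward-backward E-step; a weighted-least-squares AR M-step per state (with a
1e-8 ridge and a 1e-6 covariance floor for numerical safety); and a transition
M-step that adds `kappa` to the self-transition counts. The optimized
objective is the log-likelihood plus the sticky prior term
`kappa · Σ_k log P_kk`; EM increases this monotonically, and at `kappa = 0` it
is the log-likelihood itself, which is what the monotonicity test asserts.
Initialization is k-means on global-AR residuals concatenated with the
observations, and the initial transition matrix is sticky (0.9 diagonal): with
a uniform start, a single high-persistence AR state can absorb a slowly
switching sequence, a failure mode we observed and test against. States that
collapse to near-zero responsibility are reinitialized once from a random data
block and otherwise left (unused states are effectively the "discarded due to
low prevalence" case). Model size is chosen by the user from a twofold
cross-validated held-out log-likelihood table; the package reports the table
and makes no automatic elbow choice.

MAP state sequences take the per-frame argmax of the smoothed posteriors and
exclude frames whose maximum posterior is below 0.8. Forward-backward
posteriors are verified against exhaustive path enumeration at T = 8, K = 3 to
1e-10.

Per-trial transition features count transitions between *distinct* states
(self-transitions are dwell, not transitions; a switch includes them), with
excluded frames breaking adjacency, and are normalized to sum to one within
the trial so that single-trial decoding is possible; the per-condition
("lexical") matrix pooled over trials is produced separately for reporting.
Condition decoding uses a pooled-covariance linear discriminant with fixed
shrinkage toward the scaled identity (`λ = 0.1` by default). Shrinkage is
required, not cosmetic: simplex-normalized features have an exactly singular
pooled covariance. Significance uses stratified 10-fold cross-validation with
100 training-label shuffles per fold; the fold z-score standardizes the true
fold accuracy against its shuffle distribution, fold z-scores are averaged,
and the overall p-value is the upper normal tail. Decoder weights get the same
treatment coefficient-wise, flagged at |z| ≥ 1.96.

### A note on the attainable shuffle z-score

The fold-wise shuffle z has a structural ceiling at these sample sizes. With
20-trial test sets the shuffle accuracy SD is at least the binomial floor
(≈ 0.11), and a random permutation of 180 training labels leaves a
hypergeometric imbalance (SD ≈ 0.105) that partially aligns the shuffled
discriminant with the true boundary, widening the null in proportion to class
separation. Across idealized isotropic Gaussian features the mean fold z tops
out near 3.0 at any accuracy; on realistic transition features it sits near
2.5. The decoding *accuracy* and the calibration of the null (chance accuracy,
|z| < 2, p > 0.05 under label randomization) are the robust quantities; a mean
fold z of ~2.5 alongside accuracy ≥ 0.9 is the expected behavior of this
scheme, not a defect of the decoder.

## The synthetic generator

Because the animal dataset is large and external, every stage is validated on
synthetic sessions with full ground-truth bookkeeping. Each trial is built
as follows. The eye landmark follows a slow smoothed-triangle vertical drift
(default 1 cm/s, 4 s period): freely moving mice are never still, and a
strictly nonzero baseline vertical velocity is what makes velocity zero
crossings identify discrete movements rather than tracker noise. A Poisson
number of 500 ms motif waveforms (defaults: a 2 cm upward bob, a 2.5 cm
downward dip, and a forward lunge with a 1.8 cm bob, each with ±10% amplitude
jitter) is placed with uniform onsets, rejecting overlaps, in zones where the
drift has full magnitude and the sign of the template's initial slope — a
motif against the local drift direction would create a genuine extremum at its
onset rather than its center, and the bookkept center would not be the one the
segmentation rules anchor. The trial duration is exponential (per-condition
mean, floored at 1 s) but extended when a high motif count cannot be placed
without overlap, so motif counts stay exactly Poisson at the configured
per-trial rate while long-movement trials last longer, as they do in animals.

Head pitch and yaw are AR(1) series (per-condition pitch baseline, default
−20° binocular vs −27° monocular, stationary SD 3°, coefficient 0.95); the ear
and nose sit on a rigid segment through the eye (eye-ear distance 1 cm), so
the kinematics operations can recover the angle series exactly up to tracking
noise. Landmark noise is white with SD 0.02 cm (≈ 0.2 px at the default
10 px/cm — sub-pixel jitter typical of good markerless tracking). Eye-in-head
angles are `gain × pitch` plus white noise (default gain −1, noise 0.3°),
split as half-gain per eye in theta so vergence carries the full gain;
pupil-point tracks are rendered from those angles through the same spherical
model the analysis inverts. Outcomes are multinomial
(success/failure/abort = 0.7/0.2/0.1) and landing positions are scripted
around the gap distance so landing statistics have a known truth. Animals
carry idiosyncratic rate and pitch offsets (SD 0.15 movements/trial and 1.5°)
shared across conditions, giving the paired design its between-animal
variance. All randomness flows from one seed through counter-based per-trial
substreams, so any trial can be regenerated independently of order. When an
ARHMM truth is supplied, a latent state sequence is recorded per trial for
bookkeeping; the observation-level ARHMM benchmark is generated directly by
`simulate_arhmm()`, and the decoding benchmark uses two 4-state chains that
share emissions and differ only in where their off-diagonal transition mass
points (forward vs backward around the state cycle).

What the generator does *not* emulate: photorealistic video, biomechanical
jump dynamics, saccades or non-compensatory eye movements, tracking dropouts
beyond white noise, and any coupling between motif occurrence and the latent
ARHMM states. Passing the recovery tests therefore demonstrates that the
implementations are correct and internally consistent, not that real mouse
data satisfy the generator's assumptions.

## Numerical choices and degenerate inputs

Filter edges use reflection padding, each stage padded independently.
Exactly-zero velocities get the deterministic run-center tie-break. Coincident
eye/ear samples produce angle gaps, not errors. k-means uses 20 restarts and a
fixed seed; cluster relabeling breaks ties by cluster size then original
label. The ellipse fit centers the points before building scatter matrices and
marks degenerate frames invalid instead of failing. The LDA shuffle z uses an
SD floor of 1e-12 to avoid division by zero when a fold's null is degenerate.
Wilcoxon tests are used when a Shapiro-Wilk screen (α = 0.05) rejects
normality of the paired differences, otherwise paired t-tests; with more than
two levels a one-way ANOVA is used. Bonferroni adjustment multiplies by the
family size and caps at 1.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen to keep the full suite around
two minutes while leaving comfortable statistical margins: 1,000 random traces
for the segmentation oracle; 200 trials (rate 3/trial) for motif recovery;
200 trials per condition across 8 animals for the rate and pitch recovery;
30 trials for gaze compensation; T = 20,000 for ARHMM parameter recovery and
T = 8 for the exhaustive posterior oracle; 100 trials per condition of length
100 for the decoding benchmark; and an 8-trial-per-condition session run twice
through the full pipeline for byte-level determinism.

## Known limitations

Pixel-to-cm scale and the eye-model scale are configuration inputs, not
estimated from data. The landing-position coordinate is operationalized as
distance along the gap axis. The per-trial normalization of transition
features (rather than per condition) is required for single-trial decoding;
both normalizations are available. Mixed-effects alternatives to the
per-animal averaging rule, time-warped motif alignment, probabilistic motif
assignment, and variational or MCMC state inference are out of scope.
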