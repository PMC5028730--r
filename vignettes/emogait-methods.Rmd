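---
title: "Recognizing affective state from skeletal gait recordings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing affective state from skeletal gait recordings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emogait)
```

## The problem and the data

Walking style carries information about the walker's affective state:
cadence, arm swing and stride amplitude all shift with mood. A marker-free
depth camera (Kinect v2) reports the 3D positions of 25 skeletal joints at
30 Hz while a person walks back and forth along a footpath, giving a cheap,
non-intrusive signal from which an emotional state (for example, induced
anger versus a neutral baseline) may be classified.

`emogait` implements the full chain from raw skeleton time series to
cross-validated classification accuracy, together with a synthetic gait
generator so that every stage can be verified without access to real
recordings.

A recording (`gait_record`) is a sequence of frames, each holding 25 joints
times three coordinates, in camera coordinates (x lateral, y vertical,
z = depth from the sensor, meters). The CSV dialect is wide — one row per
frame, `frame_index` plus 75 coordinate columns in a fixed joint order —
with subject/condition/camera metadata on a leading comment line. This is
the simplest lossless layout for data that is naturally a T x (joints x 3)
matrix; values are written at 17 significant digits so round trips are
bit-exact.

## Preprocessing

The stages run in a fixed, enforced order; each is a small, separately
testable operation.

1. **Joint selection.** Fourteen joints (SpineBase, Neck, shoulders,
   elbows, wrists, hips, knees, ankles) suffice to describe gait — a
   trunk-and-limbs reduction in the tradition of point-light walker marker
   sets. A frame becomes a 42-vector and a record a T x 42 matrix.
2. **Body-centered coordinates.** Each frame is re-expressed relative to
   its own SpineBase position, so the walker's position on the footpath
   (and any rigid translation of the scene) drops out. The SpineBase
   columns become identically zero; they are *kept* so the documented
   dimensions (42 per frame, 168 per record) stay fixed. The raw
   camera-frame SpineBase track is retained separately — it is the proxy
   for the walker's position used by segmentation.
3. **Sliding-window Gaussian smoothing.** Every channel is convolved with
   the 5-tap binomial low-pass kernel `c(1, 4, 6, 4, 1)/16`. Edges are
   mirror-padded by two frames so the output keeps T rows; shortening
   records would bite into segments that are already near the 40-frame
   minimum.
4. **Differencing.** Row t becomes row t+1 minus row t: the per-frame
   displacement carries the dynamic part of gait and removes static
   posture. T rows become T-1.
5. **Segmentation.** Joint tracking degrades while the walker turns at the
   footpath ends, so turning frames are dropped and the rest is cut into
   straight-walking runs. Direction is read from the smoothed per-frame
   depth change of SpineBase: a dead band (default 2 mm/frame) marks
   turning or standing, and 15 extra frames (~0.5 s) are trimmed on each
   side of every direction change, since tracking degrades before the turn
   is geometrically visible. Runs with fewer than 40 frames are discarded —
   at 30 Hz and ~1 Hz stride frequency, 40 frames is just over one full
   stride, the minimum for the periodic features to be meaningful. Runs
   with decreasing depth (walker approaching the camera) are tagged
   `front`, increasing ones `back`.

Whether the original processing segmented before or after differencing is
not decisive here; this package follows the listed stage order (segmentation
last), mapping track frame t to differenced row t.

## Feature extraction

Human walking is periodic, so each of a segment's 42 channels is summarized
by its **main frequency** — the DFT bin of largest magnitude among
k = 1..floor(N/2) — and the complex argument at that bin (the phase). The DC
bin is excluded: after differencing the mean is essentially zero, and the
stride fundamental is the physically meaningful peak. Ties break toward the
lowest bin; constant channels return (0, 0) by convention. No windowing or
zero-padding is applied by default (the raw segment enters the DFT; a Hann
window is available via the `window` argument). One (frequency, phase) pair
per channel gives exactly 42 + 42 values per segment.

Front and back views of the same gait differ, so features are averaged
within each orientation group and concatenated:

    [front freqs (42) | front phases (42) | back freqs (42) | back phases (42)]

— 168 features per record. Phases are averaged arithmetically by default
(the plain mean of the per-segment values); a circular mean is available via
`phase_mean = "circular"` because arithmetic averaging of angles is fragile
near the ±pi wrap. A record with no front or no back segment cannot fill the
layout; the default policy drops it with a warning (a typed
`emogait_missing_orientation` condition carries the record id).

Features mix units (Hz and radians) and scales, so tables are z-score
normalized column-wise (zero-variance columns map to 0) and then reduced by
PCA, keeping the minimal leading components reaching a cumulative explained
variance of 0.95 (the default threshold; the retained dimensionality is not
fixed a priori). With ~118 instances and 168 features, reduction is what
makes the classifiers well-posed.

## Classification and cross-validation

Four classifier families are *wrapped*, not reimplemented, since the
contribution is the pipeline: Gaussian naive Bayes and SVMs from `e1071`
(RBF kernel with C = 1, gamma = 1/n_features; linear kernel with C = 1) and
a 100-tree random forest from `randomForest`. Accuracy is the pooled
proportion of correctly classified held-out instances over a seeded
stratified 10-fold cross-validation (not the mean of fold accuracies).

Two design choices deserve emphasis:

* **Leakage-safe transforms.** Normalization and PCA are fit on the
  training portion of each fold and applied to the held-out portion.
  `global_fit = TRUE` reproduces the older practice of fitting them once on
  the whole table before splitting.
* **Subject-grouped folds.** In a within-subject design the same person
  walks under both conditions. If a subject's two records straddle the
  train/test boundary, a classifier can match the test record to its
  same-subject twin in training — whose label is always the *other* class —
  producing systematic below-chance accuracy on null data (and a biased
  estimate generally). Fold assignment therefore deals all records of a
  subject to one fold; because such subjects contribute one record per
  class, the folds remain perfectly class-stratified. Subjects appearing in
  only one class are stratified by class as usual.

Records from different cameras are never mixed in one task by default (two
sensors are two measurement devices); `merge_cameras` overrides.

## The synthetic gait generator

The generator produces 25-joint records in exactly the real format, with a
minimal signal family matched to what the Fourier features measure — a
deliberate simplification, not a biomechanical claim:

* SpineBase translates along the depth axis at walking speed (default
  1 m/s) over a 6 m footpath, reversing at the ends during turn windows
  (default 2 s) in which sensor noise is inflated tenfold, so segmentation
  sees genuine direction reversals and degraded turns. At the defaults a
  straight pass lasts ~6 s ≈ 180 frames, comfortably above the 40-frame
  floor.
* Each analysis joint is SpineBase plus a rest offset plus a sinusoid at
  the stride frequency (default 1 Hz, typical adult cadence) with a second
  harmonic at amplitude fraction 0.3, left/right homologous joints in phase
  opposition; ankles and wrists carry the largest amplitudes (18 cm and
  12 cm along the walking axis). Non-analysis joints ride rigidly with
  their nearest modeled joint. Additive Gaussian noise (default 5 mm)
  models sensor jitter.
* An `emotion_effect` shifts cadence (`delta_freq`) and scales arm/leg
  amplitudes — a stand-in for the cadence/arm-swing/stride changes reported
  for affective gait. Note that because the features are frequencies and
  phases, a *uniform* amplitude scaling of a channel is invisible by
  design; discrimination in synthetic cohorts is carried by the cadence
  shift.
* `simulate_cohort` draws per-subject baselines by perturbing stride
  frequency, speed and amplitudes with a relative Gaussian spread (default
  5%, a modest inter-individual cadence variability), then generates one
  record per condition per subject — a within-subject design of the same
  shape as a two-condition study with 59 participants.

What passing tests on this generator do **not** show: robustness to real
Kinect artifacts (occlusion, joint swaps, non-stationary cadence, varying
path alignment), nor that the particular effect sizes used in tests match
real emotional modulation. They show that the pipeline recovers what it is
designed to measure and that its type-I behavior is sound.

## Numerical choices and degenerate inputs

* Smoothing requires T >= 5, differencing T >= 2; violations are errors,
  not silent truncation.
* The kernel must sum to 1 within 1e-12 (mean preservation).
* Frequency extraction requires N >= 2; constant signals return (0, 0).
* Zero-variance features are mapped to 0 by normalization; PCA errors on a
  table with no variance at all.
* Records that fail any stage inside `run_pipeline` are dropped fail-soft
  and itemized in the manifest (`status` 2), never aborting the batch.
* Every source of randomness (cohort draws, record noise, fold assignment,
  random-forest fitting) is governed by explicit integer seeds; identical
  inputs, configuration and seed reproduce outputs byte-identically.

## Problem sizes used in verification

The test suite and the acceptance script generate cohorts of 59 subjects by
two conditions (118 one-minute records at 30 Hz) for the end-to-end
discrimination and null checks — the same arithmetic as a two-camera,
59-participant study design — and smaller cohorts (3–12 subjects, 30 s
records) for pipeline plumbing checks. Oracle comparisons (from-definition
DFT, explicit convolution, covariance eigendecomposition) run on signals of
at most 256 samples and tables of 20 x 168.

## Known limitations

* Arithmetic phase averaging is the default for fidelity to the feature
  definition, but is statistically fragile; prefer `phase_mean = "circular"`
  for new analyses.
* Turn detection assumes the footpath is roughly aligned with the camera
  depth axis; strongly oblique paths would need a projected direction
  signal.
* The generator's kinematics are not physically valid (no bone-length
  constancy or ground contact) — sufficient for verifying the signal chain,
  not for biomechanics.
* Classifier hyperparameters are the wrapped libraries' defaults (recorded
  in the report); no tuning is performed.
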