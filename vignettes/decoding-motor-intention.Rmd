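---
title: "Decoding motor intention from event-related fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor intention: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intentmvpa)
```

## The experimental model

`intentmvpa` analyses an event-related design in which every trial is a
fixed three-block sequence on the repetition-time (TR = 1.5 s) grid:
fixation (1–5 TRs), a 1-TR motor-intention cue showing which hand to use,
and 3 TRs of kinesthetic motor imagery of that hand. A session holds an
equal number of left- and right-hand trials (20 per hand in the standard
design, 40 trials total) in shuffled order. Two aspects of the schedule
generator are deliberate interpretations of an under-specified protocol:

* **Fixation durations** are drawn uniformly from {1, …, 5} TRs. The
  protocol only constrains them to integral TR multiples between 1 and 5;
  uniform is the maximum-entropy choice and keeps every duration testable.
* **"Pseudo-randomized" order** is implemented as a full seeded shuffle of
  the balanced left/right list, with no maximum-run constraint, because no
  such constraint is stated. Sessions are independent schedules sharing a
  participant id (four per participant in the classic protocol; the
  package treats the number per cohort as a parameter).

The hemodynamic response is modelled purely as a **2-TR delay** (3 s) of
the block boxcar: per-TR labels are block occupancy shifted forward by
`delay_trs`, with the first `delay_trs` TRs marked unusable. No
convolution kernel is applied, because the decoding analysis itself uses
only the shift; this is an assumption of the analysis, not of the brain.

## Decoding

Trial features come from z-normalized (and optionally smoothed) BOLD:

* condition contrasts (fixation vs. intention, intention vs. imagery) use
  one sample per block, the mean of the block's delayed TRs, pooling left
  and right trials;
* laterality contrasts use the single delayed TR of one timepoint
  (intention, or imagery T1/T2/T3), labelled left = +1, right = −1.

The classifier is a soft-margin linear SVM minimising
½‖w‖² + C·Σξ with **C fixed at 10⁵**, which on z-scored features is
effectively a hard margin; the fixed value removes accuracy variation due
to regularization tuning. Solving is delegated to libsvm (`e1071`), and
the recovered `(w, w0)` are verified in the test suite against an
independent dual quadratic program. Ties at decision value 0 classify as
+1: deterministic, and a measure-zero event for continuous features.

Cross-validation defaults to **stratified 4-fold** (the evaluation scheme
the protocol names for its tables), with leave-one-out and 10-fold
available. Folds are stratified by class; when session tags exist and
partition exactly into the folds, folds follow sessions to avoid leakage.
Fold construction is fixed before any label manipulation, so relabelling
experiments (e.g. the antisymmetry test below) compare identical folds.
Reported cells are means over participants of per-participant fold means,
with the SEM taken over participants — the replication unit is documented
rather than asserted, since the original tables do not state theirs.

## Effect mapping

A linear SVM's weight alone does not say whether a voxel carries
information about the classifier output, so each voxel is scored by

E_k = w_k · Ĩ(x_k; y),  with y = wᵀx + w₀ (sign excluded),

where Ĩ(X;Y) = I(X;Y)/(H(X)+H(Y)) is normalized mutual information,
bounded in [0, 0.5] because I ≤ min(H(X), H(Y)). Numerical choices, each
covered by an oracle or property test:

* **Histogram estimator**: equal-width bins over each variable's observed
  range, 16 bins per variable by default. The bin count is configurable;
  the qualitative conclusions (sign pattern, informative-voxel ranking)
  are insensitive across 8/16/32 bins, which is the right robustness to
  ask of a histogram estimator at these sample sizes.
* **Entropy base**: log₂ (bits) for reporting; Ĩ and E_k are base
  invariant.
* **Degenerate conventions**: a constant variable occupies one bin
  (entropy 0); Ĩ := 0 when H(X)+H(Y) = 0; an all-zero effect map
  normalizes to all zeros.
* **Signed-log rescaling**: nE_k = sgn(E_k)·log(1 + |E_k|/std(E)), natural
  log, std over all E_k with the population (divide-by-N) convention. The
  absolute value inside the log is required: without it the expression is
  undefined for E_k < −std(E).
* **Group maps**: voxelwise mean of nE over folds × participants (40 maps
  for 4-fold × 10 participants), then 5 mm FWHM smoothing. Display masks
  keep the top fraction (20% default) of voxels ranked by |nE| with a
  deterministic index tie-break; ranking by signed nE is available.

The central structural property — swapping the two design labels negates
w, w₀, every E_k and every nE_k — is asserted end-to-end on synthetic data.

## Control decoders

**EMG.** Simultaneous EMG is contaminated by a TR-periodic gradient
artifact; a template averaged over the first five TR segments is
subtracted from every segment (exact for a perfectly periodic artifact).
Features are waveform lengths, WL = Σ|x_k − x_{k−1}| on the rectified
trace, from 240 ms windows. The stated "window overlap of 24 ms" is read
literally as a 216 ms step; the step is a parameter, and the 24 ms-step
(90% overlap) reading is equally expressible. Features are projected to
principal-component space (Karhunen–Loève transform, components retained
to 95% variance) and classified by a feed-forward network with a
tan-sigmoid hidden layer (10 units) and log-sigmoid outputs, one per hand,
trained by quasi-Newton batch updates with early stopping on a 20%
validation split (at most 200 optimizer iterations, patience 2). The
network is written in-package with analytic backpropagation because the
architecture — tanh hidden, per-class sigmoid outputs, validation-based
early stopping — is specified as such; it is seeded per fold and
deterministic. Evaluation is stratified 10-fold CV per timepoint.

**Gaze.** Pupil positions (60 Hz) are cleaned of blinks and of outliers
beyond median ± 3 MAD per axis, then summarized per TR by the mean (x, y)
of valid samples — a deliberate choice, since the original feature set per
TR is unstated and per-TR means are the weakest reasonable summary (they
can only under-claim ocular information). Each timepoint gets a direct
linear discriminant analysis (all variables entered together; `MASS::lda`)
under 10-fold CV; training sets whose within-class covariance degenerates
(e.g. each class collapsed to a point) fall back to the nearest-class-mean
rule, which is the LDA limit for vanishing within-class spread. Trials
whose TR has no valid sample are dropped with a warning.

## The synthetic cohort

The generator's defaults are the package's fixed study conditions: a
24 × 24 × 16 grid of 3.3 × 3.3 × 5 mm voxels (the acquisition voxel size,
desk-scale extent); eight disjoint 6 × 6 × 4 parcels standing in for the
Brodmann-composed ROIs; 60 informative voxels per informative parcel;
laterality amplitude 1.0 z-units in PPC/PMC/SMA, 0.6 in
M1/somatosensory, 0 in DLPFC/frontopolar/posterior cingulate; condition
amplitude 1.0 everywhere except 0.3 frontopolar; noise sd 1.0;
participant-level pattern jitter sd 0.2; 10 participants, one session of
20 trials per hand, seed 42. The amplitude profile reproduces the
qualitative ordering the analysis is expected to recover — strongest
laterality information parietally and premotor, intermediate in motor and
somatosensory cortex, none in the control regions — without tuning to any
particular accuracy value; the published experiment reports accuracies,
not effect sizes, so these amplitudes are stipulations, not estimates.

What the generator does **not** emulate: hemodynamic convolution shape,
physiological and scanner noise spectra (aliased respiration/cardiac,
drift), head motion, spatial autocorrelation of noise, anatomical
variability, and MNI-space registration (synthetic data are born aligned;
realignment/co-registration/normalization are out of scope because they
operate on real scanner data). Passing tests therefore demonstrate that
the *pipeline* is correct and sensitive under its own assumptions — not
that real cortex encodes intention; that evidence must come from real
data.

EMG simulation plants a fixed TR-periodic artifact waveform plus optional
laterality-locked amplitude bursts on the corresponding arm's channels;
gaze simulation plants an optional horizontal offset. Null datasets (no
planted signal) drive every decoder to chance, and the suite checks the
mean over 20 seeded repetitions against a 3-binomial-SE band around 50%.

## Preprocessing numerics

* Standard deviation convention: population (divide by N) for
  z-normalization and std(E); documented once, used consistently.
* Constant voxels z-normalize to zero and are flagged; they cannot affect
  the SVM.
* Smoothing: separable Gaussian with σ = FWHM/(2√(2 ln 2)) per axis in
  voxel units, kernel truncated at 4σ, **mirror (reflect) boundary** —
  chosen because it preserves the local mean near edges; verified against
  a direct-space triple-loop convolution. The 5 mm group-map smoothing and
  the 8 mm preprocessing smoothing are both parameters.
* Masked voxel order is column-major array order of `which(mask)`, fixed
  and documented; `unmask()` inverts it.
* z-normalization is per session by default (the per-participant scope is
  ambiguous in the protocol; per-session is the conservative reading and a
  switch away).

## Problem sizes

The test suite and the acceptance script run the full default cohort (10
participants, ~280 TRs × 9216 voxels each) for the signal-bearing checks,
20 seeded repetitions of reduced null cohorts (20 trials per hand, no
smoothing, one parcel) for the chance-level checks, and reduced EMG rates
(500 Hz) for repeated control-decoder runs — the 5000 Hz / 7500
samples-per-TR arithmetic is asserted separately at full rate. These sizes
were chosen as the smallest at which every claim under test is
statistically meaningful.

## Known limitations

* The histogram MI estimator is biased upward at small sample counts;
  effect maps from few trials should be compared only within matched
  sample sizes (as the fold-averaged group maps are).
* At C = 10⁵ the SVM is a hard margin in all but name; heavily
  overlapping classes make libsvm iterate long before converging. This is
  inherited from the fixed-C design decision, not configurable away by
  the package's tables.
* The ANN control decoder is a small batch-trained network; its accuracy
  on *signal-bearing* EMG depends on burst geometry, and only its
  null-data behaviour (chance) and strong-signal behaviour (≈100%) are
  contractual.
* `simulate_participant` returns one `bold_dataset` per session; with one
  default session the 4-fold CV stratifies within session rather than
  across sessions, which is the leakage-safe default at desk scale.
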