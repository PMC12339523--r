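---
title: "Methods: synthetic fused pulse + ECG cohorts and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic fused pulse + ECG cohorts and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pulsefuse)
```

## Scope and model

`pulsefuse` implements a complete fused wrist-pulse (PPW) + ECG analysis
chain for four-group cardiovascular classification (healthy; coronary
heart disease, CHD; CHD + hypertension; CHD + hypertension + diabetes).
Because no raw cohort is publicly available, the package pairs the
analysis chain with a *calibrated synthetic generator*: records are
simulated with known ground truth and with the class-conditional feature
statistics that the analysis is expected to recover. Everything downstream
— filtering, delineation, features, statistics, balancing, benchmarking —
operates identically on synthetic or real two-channel recordings.

### Pulse beat model

One pulse cycle is a sum of three positive components plus a notch
deepener:

* a **log-normal percussion wave** (peak time `m1`, log-sd `s1`) — zero at
  the cycle onset with all derivatives vanishing, a fast systolic upstroke
  and a slower decay, which is why it is preferred over a symmetric
  Gaussian for the dominant wave;
* **Gaussian tidal and dicrotic waves** (amplitudes `a2`, `a3`, centers
  `mu2`, `mu3`, sds `s2`, `s3`);
* an **inverted Gaussian notch component** between the tidal and dicrotic
  centers whose depth is a fraction of the percussion amplitude.

Ramp corrections pin the cycle to zero at both ends (a quartic end ramp,
so the slowly decaying tail is never pushed below zero) and a small
fast-rising foot pedestal (2% of the percussion amplitude over the first
5% of the cycle) gives every cycle a sharp V-shaped minimum exactly at its
boundary — without it the inter-beat trough is nearly flat and a minimum
search floats by tens of milliseconds even on noiseless signals. The superposition exhibits, in order:
onset trough, percussion peak (H1), pre-tidal shoulder (H2, an inflection
of the descending limb), tidal peak (H3), dicrotic notch (H4) and dicrotic
peak (H5). Ground-truth fiducials are *located numerically* on the
noiseless waveform by derivative sign-change search — the same definitions
the analysis-side delineator uses — so truth and estimate are comparable
point by point.

### ECG beat model

One beat is a sum of five Gaussian waves (P, Q, R, S, T; Q and S
negative). Wave onsets/offsets in the ground truth are defined at the
point where a wave's component falls to 1% of its peak. The QRS complex is
carried by a broad R wave whose width is set during calibration (below);
the narrow Q and S waves are placed symmetrically so that the
1%-convention ground-truth QRS duration equals the group's published
median. P-wave duration is fixed at 100 ms (not tabulated in the source
material); ST, PR and QT layouts are derived in closed form from the
published interval medians.

### Records and cohorts

A record concatenates beats with i.i.d. Gaussian beat-to-beat period
jitter whose sd equals the group's published pulse-SDNN median — the
simplest model matching the only printed variability statistics. With
i.i.d. jitter the implied rMSSD is √2·SDNN, which falls inside every
group's published rMSSD interquartile range, so no extra correlation
structure is imposed. The two channels are phase-locked: each pulse onset
trails its R peak by a fixed 0.2 s transit delay (no extracted feature is
cross-channel, so the value is inconsequential).

The subject-level mean period is drawn from the group's published
pulse-period distribution (location solved so the *truncated median*
equals the printed median; spread = IQR/1.349; truncation 0.62–1.30 s).
Drawing the period — rather than heart rate — keeps the cohort medians of
both the pulse period and the mean-RR interval inside their published
IQRs simultaneously (the two quantities must coincide in a phase-locked
record, and their printed medians differ slightly); the implied group-1
mean heart rate still lands within 2 bpm of the published value.
Demographics (sex, age, BMI, SBP, DBP) are truncated Gaussians whose
pre-truncation locations are solved so the truncated means equal the
published group means — without this, plausibility truncation (e.g. age
20–75) would bias the young, high-variance healthy group by +1.5 years.

Noise is additive: a respiratory-band sinusoid (0.25 Hz), 50 Hz powerline,
20–40 Hz band-limited EMG noise, and white noise; the `"clinical"` profile
uses amplitudes 0.30 / 0.10 / 0.05 / 0.01 relative to unit peak
amplitudes, routed predominantly to the channel each disturbance
physically affects. Per-subject random streams are derived from the master
seed by counter splitting, so a subject's record is invariant to cohort
composition.

## Preprocessing

* PPW: 3rd-order 8 Hz Butterworth low-pass, then a natural cubic spline
  through the detected pulse troughs is subtracted (baseline drift).
* ECG: baseline extraction by a 3rd-order low-pass in the 0.2–0.5 Hz band
  (default **0.5 Hz**: at 0.25 Hz drift it removes ~98% of the wander,
  whereas a 0.3 Hz cutoff leaves a quarter of it), then two-stage
  filtering: 40 Hz (order 4) for R detection and 20 Hz (order 4) for all
  other fiducials.

All filters are applied forward–backward (zero phase) with reflect
padding: group delay would otherwise bias every timing feature. A
consequence worth stating plainly: the 20 Hz stage *widens* narrow QRS
complexes — no delineator can recover sub-10-ms accuracy of 1%-convention
QRS bounds through it. The package resolves this by calibrating the
generator against the *full pipeline* (next section) rather than by
weakening the filters the method prescribes.

## Delineation

Pulse cycles: systolic peaks by an adaptive amplitude threshold with a
0.4 s minimum separation; onsets as inter-peak minima; per cycle, H1 is
the global maximum, H4 the most prominent local minimum in 0.15–0.6 of the
cycle, H3 the largest local maximum between H1 and H4 (first-derivative
inflection as fallback), H2 the first zero of the second derivative
between H1 and H3, H5 the largest local maximum after H4. Amplitudes are
measured above the onset level; missing landmarks are flagged, never
errors. The pulse-period series for P-SDNN/P-rMSSD is measured between
successive maximum-upslope points rather than the troughs themselves: the
upstroke is the sharpest landmark of the cycle, and under respiratory
drift the flat diastolic trough wanders by tens of milliseconds while the
upslope spacing (numerically identical in a rigid beat train) is stable.

ECG beats: R peaks by a derivative-energy detector (squared differences
band-limited to 5–15 Hz so residual EMG noise cannot trigger spurious
beats, 150 ms integration, adaptive threshold, 0.25 s refractory period,
local-maximum refinement). Per beat, Q/S are minima within ±80 ms of R;
QRS bounds are the points where the signal returns within 3% of the R
amplitude (walking outward from R, sustained over 3 samples); P and T
peaks in the windows [R−300, R−80] ms and [R+120, R+min(0.6·RR, 450)] ms;
P/T onsets/offsets by amplitude-threshold crossings (4% of the P
amplitude, 2.5% of the T amplitude) referenced to the *local floor* of
each search window — the residual post-filter baseline ripple (~1% of R)
offsets flat segments from any single global isoelectric estimate, which
defeats small fixed thresholds. A slope-threshold variant for the QRS
bounds was tried first and abandoned: its crossing position responds
discontinuously to morphology because the threshold competes with the
Q-wave's own maximum slope. Amplitudes are reported relative to the
P-onset level (the zero-line convention).

## Calibration

Generator presets per group are frozen constants obtained by a two-stage
procedure:

1. **Beat shapes** (pulse): Nelder–Mead over the nine bump parameters so
   the noiseless single-beat truth hits the published group medians of
   H2/H1, H3/H1, H5/H1, W1, W2 and pipeline-corrected targets of T1, T4
   (a positivity penalty keeps the notch above the onset level).
2. **Pipeline offsets**: group medians of T1, T4, QRS, ST, PR, QT are
   measured through the complete pipeline on pilot cohorts; the residual
   biases (filter widening, threshold conventions; all ≤ 7 ms after the
   delineator design above) are folded back into the component layout.

The result: on cohorts of 100 subjects per group, the medians of T, T1,
T4, QRS, ST, PR and QT all fall inside the published interquartile ranges
under both the clean and the clinical noise profile, and mean group-1
heart rate is within 2 bpm of the published mean.

## What the synthetic data does and does not show

The generator reproduces: class-conditional time-domain feature medians,
beat-to-beat variability magnitudes, demographic moments, realistic noise
types, and exact ground truth for recovery testing. It does **not**
emulate: arrhythmia/ectopy, morphology correlations across features
beyond what the bump model induces, sensor pressure-sweep effects,
non-stationary noise, or inter-feature correlation structure of real
cohorts. Passing tests therefore demonstrate the *pipeline's* correctness
and robustness, not clinical-grade performance on real patients; the
published real-cohort headline accuracies are out of reach by
construction, since the raw data are unavailable.

## Statistics, balancing, benchmarking

* `compare_groups()`: per-feature Shapiro–Wilk screen (α = 0.05 in every
  group) routes to one-way ANOVA (mean ± SD summaries) or Kruskal–Wallis
  (median (Q1–Q3)); categorical features use the chi-square test; pairwise
  flags vs reference groups use Welch t / Mann–Whitney with raw p-values
  (no correction by default, Holm optional). The source material applies a
  two-sample rank test to four groups; the omnibus Kruskal–Wallis plus
  pairwise comparisons is the only coherent reading and is what the
  package computes.
* `chisq_power_n()`: smallest N with noncentral chi-square power
  ≥ target at noncentrality N·w²; monotone in all arguments; for
  w = 0.30, α = 0.05, power 0.80, df = 78 it returns 405. The df follow
  the source design `(4−1)×(27−1)`; the 27 is a design input, not
  recomputed.
* `smote_balance()`: z-scored Euclidean nearest neighbors (k = 5),
  synthesis `x + u(x_nn − x)`, seeds drawn uniformly with replacement
  until each minority class reaches the majority size; originals first
  and unchanged. Balancing happens *inside training folds only* by
  default (`smote_before_split = TRUE` reproduces the leakier
  balance-then-split protocol whose use in the source cannot be ruled
  out).
* Occasional missing feature values (a subject whose notch-dependent
  features could not be measured) are imputed with the column median at
  the modeling boundary.
* `train_eval_cv()`: stratified outer CV (default 5-fold), inner 3-fold
  grid search per training fold; tree ensembles search trees
  {50,100,150,200} × min leaf {1,2,3}; the RBF SVM searches C and gamma on
  a log10 grid over 1e-8…1e8 at step 10² (9 points per axis — a coarser
  resolution than an exhaustive unit-decade grid, chosen to keep a full
  benchmark tractable on one CPU; the search *range* is the prescribed
  one). Headline metrics come from the pooled out-of-fold confusion
  matrix; SVM class scores use pairwise-coupling probabilities.
* `rf_importance()` (500 trees, Gini, normalized to sum 1) +
  `sfs_select()` (features added strictly in ranking order, fixed folds
  across prefix lengths, shortest-prefix-at-maximum selection — ties
  resolve to the simpler model) + `fsrf_cv()` (nested variant redoes
  ranking/selection inside each training fold; the non-nested variant
  mirrors the select-once-then-cross-validate protocol of the source).

## Numerical choices and degenerate inputs

Sample standard deviations (n−1) throughout; times in seconds internally
(0-based sample indices), variability statistics in ms; cycles are
half-open `[onset, next_onset)`; T2/T3 are defined as times to the H2/H3
landmarks by symmetry with T1/T4 and excluded from calibration; widths
W1/W2 are interpreted at amplitude levels 2/3·H1 and 4/5·H1 above the
onset level; As/Ad areas are measured above the onset level (not absolute
zero). Degenerate inputs fail loudly and specifically: flat signals, < 3
cycles/beats, < 4 spline anchors, cutoffs at/above Nyquist, minority
classes ≤ k, constant labels, classes smaller than the fold count.
Zero-variance features are skipped with a flag rather than tested.

## Problem sizes used by the test suite

The shipped tests run cohorts of up to 100 subjects per group at 15–20 s
record length for calibration checks, 12 s records for recovery checks,
and 30 replicate seeds of a 100 × 40 (4 informative + 36 noise features)
planted-signal design for the feature-selection comparison. These sizes
are the package's choices for a reproducible desk-scale validation; all
of them can be scaled up through the same functions.

## Known limitations

* The 1%-of-component onset/offset convention for synthetic ECG truth is
  not exactly recoverable through a 20 Hz filter for the P and T waves;
  residual fiducial biases are kept under ~15 ms and interval biases under
  ~7 ms by the threshold design, and are absorbed by calibration.
* The pulse onset trough of the beat model is flat; under strong drift
  its exact sample is ill-defined (hence the upslope-based period
  series).
* Group-conditional feature *spreads* (IQuartile widths) are not
  calibrated — only medians and the variability statistics are.
* SMOTE assumes locally convex minority regions, as always.
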