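---
title: "Detecting premature ventricular contractions with beat features and a bagged CART forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting premature ventricular contractions with beat features and a bagged CART forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcforest)
```

## The problem

A premature ventricular contraction (PVC) is an ectopic beat originating in
the ventricles. On a surface ECG it shows a characteristic constellation:
the beat arrives early (short preceding RR interval) and is followed by a
compensatory pause, the P wave is absent, and the QRS complex is wide and
often taller (or inverted) relative to normal beats. `pvcforest` implements
a complete beat-level PVC detector for single-lead recordings sampled at
360 Hz, in the MIT-BIH arrhythmia database layout: signal preprocessing,
R-peak detection, beat delineation, feature extraction, class rebalancing
and an interpretable ensemble classifier — every stage written in R and
testable offline against a bundled synthetic generator.

## Pipeline and models

### Wavelet denoising

Signals are denoised in the wavelet domain with an orthonormal periodized
discrete wavelet transform. The default mother wavelet is the 8th-order
Daubechies filter (db8); `select_wavelet()` implements filter selection by
maximizing the peak absolute normalized cross-correlation between the
signal and each candidate's scaling filter. The thresholding rule is not
part of the published method description, so the package adopts the
standard universal threshold `sigma * sqrt(2 log n)` with soft shrinkage on
all detail levels and `sigma = median(|d1|)/0.6745`; both the rule and the
mode are configurable through `denoise_config()`. Five decomposition
levels at 360 Hz place the coarsest detail band at roughly 5.6–11 Hz, so
QRS energy is retained while high-frequency noise is shrunk. Signals whose
length is not a multiple of `2^levels` are edge-padded and truncated after
reconstruction; the transform on unpadded lengths is exactly orthogonal
(energy-conserving to machine precision), which the tests assert.

### R-peak detection

`detect_r_peaks()` is the classic Pan–Tompkins chain: a zero-phase 5–15 Hz
Butterworth band-pass designed at run time for the given sampling rate, a
five-point derivative, elementwise squaring, and a 150 ms moving-window
integral, followed by adaptive dual-threshold decision logic with a 200 ms
refractory period, slope-based T-wave rejection inside 360 ms, and
search-back at half threshold when no beat is seen within 1.66 times the
running RR average. Two design details matter on smooth, low-noise
signals: a larger integrated peak arriving inside the refractory window
*supersedes* the previous acceptance (otherwise a P-wave trigger can
capture the refractory window and blank the true R peak), and when two
refined detections collide within the refractory spacing the one with the
larger absolute amplitude is kept. Each accepted decision is mapped back
through the integrator delay and refined to the local extremum of the
input within ±75 ms. Detections are scored against reference beats by
greedy nearest-first one-to-one matching within 150 ms, the standard
beat-matching tolerance.

### Beat windows and QRS delineation

Each beat is the inclusive window `[R - 100, R + 150]` samples — 251
samples at 360 Hz, with local fiducials P_start = 1, R = 101, T_end = 251
(indices are 1-based throughout the R API). QRS onset and offset are
localized by a sliding-window variance search: at candidate `X_i` the
trailing five-sample half-window variance `S1` and leading half-window
variance `S2` (population variance, division by *n*) are compared, and the
onset is the first index where `S1 < S2`, `S1` is within a flatness
tolerance (a stationary baseline), and the five following samples are
strictly monotone — the QRS take-off. The offset search mirrors this
predicate and scans forward from R within `[R, T_end]`. Two parameters are
deliberately scale-free because "fluctuates around zero" has no published
magnitude: the flatness tolerance defaults to 2% of the largest
half-window variance in the beat (floored at 1e-6 mV²), so amplitude
rescaling and baseline shifts do not change the result. When no index
qualifies (e.g. a flat beat), the boundaries fall back to fixed 40-sample
(~111 ms) half-widths and the beat is flagged — every beat must yield a
feature vector. A subtlety the tests document: the onset and offset
predicates are exact mirror images, but both searches return the *first*
qualifying index in opposite scan directions, so on ramp-like beats whose
acceptance set has two adjacent members the "mirror identity" between the
two searches holds at the level of acceptance sets rather than single
indices.

### Features

Seven per-beat features are computed from the fiducials: `R_amp` (signed
amplitude of the denoised signal at R — PVC beats may be negative-going),
the `PR`, `QRS` and `QT` intervals in seconds, `QRS_area = QRS * R_amp`
(mV·s), and the `pre_RR`/`post_RR` intervals from the R-peak train (the
first and last beats are excluded since they lack one interval). No
normalization is applied anywhere: the forest is scale-equivariant, which
is one reason it suits this feature set. The default classifier subset is
`pre_RR`, `post_RR`, `QRS_area`, `R_amp` — the four features that
`single_feature_importance()` ranks highest on generator data, mirroring
their clinical salience for PVC.

### SMOTE rebalancing

PVC is a minority class (about 13:1 against in the training half of the
MIT-BIH split). `smote_balance()` implements synthetic minority
oversampling: for each minority sample, one of its k = 5 nearest minority
neighbours (Euclidean distance, self excluded, ties by row order) is drawn
and a synthetic point is placed uniformly at random on the connecting
segment. The integer magnification `N = floor(need/m)` is topped up by
residual draws from random minority base points so the target
majority:minority ratio is hit *exactly* — published target ratios
(8:1, 4:1, 1:1 from 13:1) are not integer multiples, so pure integer
magnification cannot reach them. k = 5 is the literature default; the
draw order is fixed and documented so balanced sets are byte-identical
under a fixed seed.

### The bagged CART forest

The classifier is written from scratch: `n_trees = 120` CART trees, each
grown on a bootstrap sample of the training set (n draws with
replacement), with Gini-impurity splitting. Continuous features are split
at midpoints of consecutive distinct sorted values — the published Gini
index is stated for discrete attributes with V values, and binary
thresholding is the standard CART treatment of continuous ones. Stopping
rules are `min_split = 100` and `min_leaf = 30` (the published tuned
values); there is no pruning. Candidate features are re-drawn per split
(`mtry = "sqrt"` by default; `"all"` gives pure bagging — the source
method does not state its feature subsampling, so both are exposed). Ties
are deterministic: splits by lowest feature index then lowest threshold,
leaf predictions and ensemble votes to the non-PVC class (the safer
default for a screening application is debatable; it is documented and
configurable by relabelling). Each tree's in-bag multiset is recorded, so
the out-of-bag (OOB) generalization error — each sample voted on only by
trees that never saw it — is computed at fit time and reported by
`glance()`.

### Evaluation

`evaluate_predictions()` reports accuracy, positive predictive value,
sensitivity, specificity, and Youden's index `gamma = Se + Sp - 1`, with
PVC as the positive class. A metric with a zero denominator is reported
as `NA` with a warning, never as 0, so averages are not silently
inflated. `gamma` is prevalence-invariant, which is why it is the right
summary for the imbalance experiments.

## The synthetic generator

`generate_record()` synthesizes a labelled two-class beat stream: each
normal beat is a sum of Gaussian bumps (P, Q, R, S, T) with fixed default
centres, widths and amplitudes; a PVC suppresses the P wave, widens the
QRS by 2.5x, scales the R amplitude by 1.4x (optionally sign-flipped),
arrives at 0.7x the base RR and is followed by a compensatory pause
preserving the two-interval sum at twice the base RR. White noise,
sinusoidal baseline wander and 50/60 Hz powerline interference are added
after beat synthesis. `generate_feature_table()` draws the four classifier
features directly from class-conditional diagonal Gaussians whose means
are derived from those same morphology knobs (base RR 0.8 s; PVC pre_RR
0.56 s, post_RR 1.04 s, QRS area 0.385 vs 0.11 mV·s, R amplitude 1.54 vs
1.10 mV), with spreads chosen so that the single-feature separations rank
pre_RR > post_RR > QRS_area > R_amp — the same importance ordering the
full pipeline exhibits. Because the generating model is a Gaussian pair,
the Bayes-optimal rule is available in closed form
(`bayes_rule_labels()`) and upper-bounds any trained classifier, which
the tests exploit as an analytic oracle.

What the generator does *not* emulate: real QRS morphology variation
within a class, non-PVC arrhythmias, atrial activity abnormalities,
electrode artefacts, or non-stationary noise. Tests passing on synthetic
data therefore demonstrate the correctness of the machinery — decoding,
detection, delineation, balancing, tree growth, voting, OOB bookkeeping —
not clinical performance; the published MIT-BIH figures are reproducible
only through the `reproduce_mitbih()` harness with a user-supplied local
copy of the database (never downloaded by this package).

## Numerical choices and problem sizes

All randomness flows through explicit seeds (`set.seed` scoped inside each
function, restoring the caller's RNG state); fits, balanced sets and
generated records are byte-identical across runs with the same seed. The
test suite uses deliberately modest problem sizes — 300-beat records for
detector scoring, 100 constructed beats for boundary localization, 200
random instances for the exhaustive split-search oracle, n = 4000 with 200
trees for the OOB-versus-holdout comparison, and a 7000-beat 13:1 training
table against a 14000-beat 13:1 test table for the end-to-end and
imbalance experiments — sizes at which every check runs in seconds to a
couple of minutes on one core while keeping binomial noise on the reported
rates small. For the imbalance trend (training at 13:1, 8:1, 4:1, 1:1 and
testing on a fixed imbalanced set), gamma differences between adjacent
ratios are of the same order as single-run sampling noise, so the trend
check averages gamma over three replicate seeds per ratio rather than
comparing single fits.

## Known limitations

* Only WFDB format 212 and MIT-style beat annotations are supported (plus
  a two-column text dialect); formats 16/80/310 and multi-segment records
  are out of scope.
* The boundary search assumes the fixed 251-sample beat geometry of a
  360 Hz recording; other sampling rates rescale the feature intervals but
  the window constants are tied to the published layout.
* The forest handles exactly two classes; the five AAMI classes are
  collapsed to PVC / non-PVC before training.
* Tree growth is depth-unbounded (stopping on purity and the size rules
  only), which is faithful to the method but can be slow on very large
  tables with tiny `min_leaf`.

## A worked example

```{r example, eval = FALSE}
library(pvcforest)

train <- generate_feature_table(n = 7000, ratio = 13, seed = 11)
test  <- generate_feature_table(n = 3500, ratio = 13, seed = 12)

pipe <- run_pvc_pipeline(train, test, balance_ratio = 1, seed = 5)
pipe$report
glance(pipe$forest)
autoplot(pipe$forest)
```
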