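# pvcforest

Beat-level detection of premature ventricular contractions (PVC) in
single-lead ECG recordings, for researchers working with the MIT-BIH
arrhythmia database layout (360 Hz, WFDB format 212) or with simulated
beat streams.

A PVC is an ectopic ventricular beat: it arrives early (short preceding RR
interval), is followed by a compensatory pause, lacks a P wave, and has a
wide, often taller QRS complex. `pvcforest` turns those physiological
signatures into a classification pipeline in which every stage is plain,
tested R:

1. **I/O** — WFDB headers, format-212 signals (two 12-bit two's-complement
   samples per 3 bytes), MIT binary and text beat annotations; AAMI class
   collapse (N, S, V, F, Q) to the binary PVC label; the published
   DS1/DS2 train/test split with the four paced records excluded.
2. **Denoising** — orthonormal periodized Daubechies DWT (db8 default,
   5 levels) with universal-threshold soft shrinkage; data-driven wavelet
   selection by scaling-filter cross-correlation.
3. **R-peak detection** — Pan–Tompkins: 5–15 Hz band-pass, derivative,
   squaring, 150 ms moving-window integration, adaptive dual thresholds
   with 200 ms refractory period, T-wave rejection and search-back;
   detections scored against reference beats within 150 ms.
4. **Delineation** — beats are the inclusive window [R−100, R+150]
   (251 samples); QRS onset/offset located by a sliding-window variance
   search: a stationary-baseline half-window (variance S1, "flat") next to
   an active half-window (S2), followed by a strictly monotone 5-sample
   run.
5. **Features** — `R_amp`, `PR`, `QRS`, `QT`, `QRS_area = QRS · R_amp`,
   `pre_RR`, `post_RR`; default classifier subset
   `{pre_RR, post_RR, QRS_area, R_amp}`.
6. **Balancing** — SMOTE to an exact target ratio: each minority sample is
   interpolated toward one of its k = 5 nearest minority neighbours,
   `x_new = x + r·(x′ − x)`, `r ~ U(0,1)`.
7. **Classifier** — a from-scratch bagged CART forest: Gini impurity
   `1 − Σ p_k²`, splits minimizing the size-weighted child impurity
   `Σ_v (|D_v|/|D|)·Gini(D_v)` over midpoint thresholds, defaults
   `n_trees = 120`, `min_split = 100`, `min_leaf = 30`, majority vote, and
   out-of-bag error from the recorded bootstrap multisets.
8. **Evaluation** — Acc, PPV, Se, Sp and Youden's `γ = Se + Sp − 1`, with
   PVC positive.

A synthetic generator (`generate_record()`, `generate_feature_table()`)
produces labelled records and feature tables with the PVC phenomenology
above, so the whole pipeline is testable without downloading clinical
data; `reproduce_mitbih()` runs the real experiment against a
user-supplied local copy of MIT-BIH.

## Worked example

```r
library(pvcforest)

# a 13:1 imbalanced training table and an untouched imbalanced test table
train <- generate_feature_table(n = 7000, ratio = 13, seed = 11)
test  <- generate_feature_table(n = 3500, ratio = 13, seed = 12)

pipe <- run_pvc_pipeline(train, test, balance_ratio = 1, seed = 5)
pipe$report
#>      TP   TN    FP  FN    Acc      PPV    Se    Sp gamma
#> 1   243 3237    13   7 0.994 0.949219 0.972 0.996 0.968

glance(pipe$forest)
#>   n_train n_features n_trees min_split min_leaf mtry  oob_error oob_coverage
#> 1   13000          4     120       100       30 sqrt 0.00430769            1
```

The report reads: of 250 true PVC beats in the test set, 243 were caught
(sensitivity 0.972) with 13 false alarms (PPV 0.949); specificity 0.996
gives Youden's γ = 0.968. The forest's out-of-bag error (0.43%) is its
own internal generalization estimate on the balanced training set.

Signal-level use follows the same grammar:

```r
sim <- generate_record(synth_config(n_beats = 300, pvc_fraction = 0.1, seed = 42))
rf  <- record_features(sim$record, annotations = sim$annotations)
score_detections(rf$r_peaks, sim$annotations$sample, fs = 360)
#>   all correct wrong missed Se PPV
#> 1 300     300     0      0  1   1
```

A thin command-line front end over these functions lives in
`inst/cli/pvc.R` (`simulate`, `detect`, `features`, `balance`, `train`,
`evaluate`, `pipeline`, `reproduce-mitbih`).

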