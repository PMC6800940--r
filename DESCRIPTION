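Package: pvcforest
Title: Premature Ventricular Contraction Detection with Beat Features and a Bagged CART Forest
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for detecting premature ventricular
    contractions (PVC) in single-lead ECG recordings: WFDB record input
    and output (format 212 signals, MIT-style beat annotations), wavelet
    denoising with Daubechies filters, Pan-Tompkins R-peak detection,
    heartbeat segmentation with a sliding-window variance search for QRS
    onset and offset, per-beat feature extraction (RR intervals, R
    amplitude, QRS duration and area, PR and QT intervals), SMOTE
    oversampling for class balance, and a from-scratch bagged CART
    random forest with Gini splitting and out-of-bag error estimation.
    A synthetic ECG generator with ground-truth beat labels makes every
    stage testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
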