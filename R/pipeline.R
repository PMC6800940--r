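#' Per-record signal pipeline: denoise, detect, extract features
#'
#' Runs the signal half of the pipeline on one record: wavelet denoising,
#' Pan-Tompkins R-peak detection, beat segmentation with QRS boundary
#' localization, and feature extraction (labelled when annotations are
#' given).
#'
#' @param record An `ecg_record`.
#' @param annotations Optional annotation tibble for labelling.
#' @param denoise Apply wavelet denoising before detection (default TRUE).
#' @param denoise_cfg A [denoise_config()].
#' @param boundary_cfg A [boundary_config()].
#' @param tolerance_ms Annotation-matching tolerance.
#' @return List with `features` (tibble), `r_peaks`, `denoised` (numeric).
#' @export
record_features <- function(record, annotations = NULL, denoise = TRUE,
                            denoise_cfg = denoise_config(),
                            boundary_cfg = boundary_config(),
                            tolerance_ms = 150) {
  stopifnot(inherits(record, "ecg_record"))
  x <- if (denoise) denoise_signal(record$samples, denoise_cfg) else record$samples
  peaks <- detect_r_peaks(x, record$fs)
  feats <- extract_features(
    x, peaks, fs = record$fs, annotations = annotations,
    boundary = boundary_cfg, tolerance_ms = tolerance_ms
  )
  list(features = feats, r_peaks = peaks, denoised = x)
}

#' Run the full classification pipeline on feature tables
#'
#' Projects both tables onto the chosen feature subset, SMOTE-balances the
#' training set to the target ratio, fits the bagged CART forest, predicts
#' the (untouched, imbalanced) test set and reports the five evaluation
#' metrics. All randomness is governed by `seed`.
#'
#' @param train,test Labelled feature tibbles (logical `label`).
#' @param feature_subset Character vector of feature names (default: the
#'   four-feature classifier subset).
#' @param balance_ratio Target majority:minority ratio for SMOTE
#'   (default 1); `NULL` skips balancing.
#' @param smote_k SMOTE neighbour count.
#' @param n_trees,min_split,min_leaf,mtry Forest parameters (defaults 120,
#'   100, 30, `"sqrt"`).
#' @param seed RNG seed for SMOTE and the forest.
#' @param out_dir Optional directory; when given, writes
#'   `train_balanced.csv`, `model.json` and `report.json` there.
#' @return List of class `pvc_pipeline`: `forest`, `train_balanced`,
#'   `predictions` (logical), `report` (one-row metrics tibble).
#' @export
run_pvc_pipeline <- function(train, test,
                             feature_subset = default_feature_subset(),
                             balance_ratio = 1, smote_k = 5L,
                             n_trees = 120L, min_split = 100L,
                             min_leaf = 30L, mtry = "sqrt", seed = 1L,
                             out_dir = NULL) {
  train <- select_features(train, feature_subset)
  test <- select_features(test, feature_subset)
  balanced <- if (is.null(balance_ratio)) {
    dplyr::mutate(train, synthetic = FALSE)
  } else {
    smote_balance(train, ratio = balance_ratio, k = smote_k, seed = seed)
  }
  forest <- pvc_forest(
    balanced, n_trees = n_trees, min_split = min_split,
    min_leaf = min_leaf, mtry = mtry, seed = seed
  )
  pred <- predict(forest, test)
  report <- evaluate_predictions(test$label, pred)
  out <- structure(
    list(forest = forest, train_balanced = balanced,
         predictions = pred, report = report),
    class = "pvc_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(balanced, file.path(out_dir, "train_balanced.csv"),
                     row.names = FALSE)
    forest_to_json(forest, file.path(out_dir, "model.json"))
    jsonlite::write_json(as.list(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pvc_pipeline <- function(x, ...) {
  cat("<pvc_pipeline>\n")
  print(x$forest)
  cat("test-set metrics:\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

# Published reference values for this pipeline on the MIT-BIH DS1/DS2
# split (classification on DS2; detector totals over the 44 records).
.mitbih_reference <- list(
  classification = c(Acc = 96.38, PPV = 95.46, Se = 97.88, Sp = 97.56,
                     gamma = 95.45),
  detector = c(Se = 0.9963, PPV = 0.9941)
)

#' Reproduce the MIT-BIH experiment from a local database copy
#'
#' Runs the full pipeline on a user-supplied local copy of the MIT-BIH
#' arrhythmia database (never downloaded by this package): per-record
#' Pan-Tompkins detection scores, DS1 training (SMOTE-balanced 1:1), DS2
#' testing, and the five metrics alongside the published reference values
#' for manual comparison. Records missing from the directory are listed
#' and skipped.
#'
#' @param directory Directory containing `<record>.hea/.dat/.atr` files.
#' @param lead Lead name (default `"MLII"`).
#' @param seed RNG seed.
#' @param ... Passed to [run_pvc_pipeline()].
#' @return List with `detection` (per-record score tibble), `report`
#'   (metrics with reference deltas) and `missing` (absent record names).
#' @export
reproduce_mitbih <- function(directory, lead = "MLII", seed = 1L, ...) {
  if (!dir.exists(directory)) {
    rlang::abort(paste0(
      "MIT-BIH directory not found: ", directory,
      " (supply a local copy of the database; it is never downloaded)"
    ))
  }
  all_names <- c(.ds1_records, .ds2_records)
  present <- all_names[file.exists(file.path(directory, paste0(all_names, ".hea")))]
  missing <- setdiff(all_names, present)
  if (length(present) == 0L) {
    rlang::abort("no usable records found in the directory")
  }
  if (length(missing)) {
    rlang::inform(paste0(
      "missing record(s), running on ", length(present), "/44: ",
      paste(missing, collapse = ", ")
    ))
  }

  per_record <- purrr::map(present, function(name) {
    rec <- read_wfdb_record(directory, name, lead = lead, ann_dialect = "mit")
    rf <- record_features(rec$record, annotations = rec$annotations)
    score <- score_detections(rf$r_peaks, rec$annotations$sample, rec$record$fs)
    list(name = name, features = rf$features, score = dplyr::mutate(score, record = name))
  })
  detection <- dplyr::bind_rows(purrr::map(per_record, "score"))

  ds <- partition_records(present)
  tbl_of <- function(which) {
    dplyr::bind_rows(purrr::map(
      per_record[ds$dataset == which],
      ~ dplyr::select(.x$features, -dplyr::any_of(c("beat", "r_global")))
    ))
  }
  train <- tbl_of("DS1"); test <- tbl_of("DS2")
  if (nrow(train) == 0L || nrow(test) == 0L) {
    rlang::abort("need records from both DS1 and DS2 to train and test")
  }
  pipe <- run_pvc_pipeline(train, test, seed = seed, ...)
  ref <- .mitbih_reference$classification
  report <- pipe$report |>
    dplyr::mutate(dplyr::across(c("Acc", "PPV", "Se", "Sp", "gamma"), ~ 100 * .x)) |>
    tidyr::pivot_longer(c("Acc", "PPV", "Se", "Sp", "gamma"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("metric", "value") |>
    dplyr::mutate(reference = ref[.data$metric],
                  delta = .data$value - .data$reference)
  list(detection = detection, report = report, missing = missing,
       coverage = length(present) / 44)
}
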