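# The seven per-beat features, in canonical column order.
FEATURE_NAMES <- c("pre_RR", "post_RR", "R_amp", "PR", "QRS", "QT", "QRS_area")

#' The default four-feature subset used for classification
#'
#' The RR intervals, QRS area and R amplitude carry most of the
#' PVC-discriminating information and are the default classifier input.
#'
#' @return Character vector of feature names.
#' @export
default_feature_subset <- function() c("pre_RR", "post_RR", "QRS_area", "R_amp")

#' Morphology features of segmented beats
#'
#' Computes, per beat, from its fiducial points: `R_amp` (signed amplitude
#' at the R sample of the denoised beat, mV), `PR = (QRS_start - P_start)/fs`,
#' `QRS = (QRS_end - QRS_start)/fs`, `QT = (T_end - QRS_start)/fs` (all
#' seconds) and `QRS_area = QRS * R_amp` (mV s).
#'
#' @param beats Beat tibble from [locate_qrs()] (fiducials must be set).
#' @param fs Sampling rate in Hz (360 for MIT-BIH).
#' @return The beat tibble with columns `R_amp`, `PR`, `QRS`, `QT`,
#'   `QRS_area` appended.
#' @export
beat_features <- function(beats, fs = 360) {
  if (anyNA(beats$qrs_start) || anyNA(beats$qrs_end)) {
    rlang::abort("QRS fiducials are unset; run locate_qrs() first")
  }
  p_start <- 1L
  t_end <- BEAT_LEN
  r_amp <- purrr::map_dbl(beats$samples, R_LOCAL)
  qrs <- (beats$qrs_end - beats$qrs_start) / fs
  beats |>
    dplyr::mutate(
      R_amp = r_amp,
      PR = (.data$qrs_start - p_start) / fs,
      QRS = qrs,
      QT = (t_end - .data$qrs_start) / fs,
      QRS_area = .data$QRS * .data$R_amp
    )
}

#' RR-interval features from the R-peak train
#'
#' Beat `j` gets `pre_RR = (R_j - R_(j-1))/fs` and
#' `post_RR = (R_(j+1) - R_j)/fs`. The first beat (no predecessor) and the
#' last beat (no successor) are excluded.
#'
#' @param r_peaks Sorted integer vector of R-peak samples.
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `beat` (index into `r_peaks`), `pre_RR`,
#'   `post_RR` (seconds); empty (with a warning) when fewer than 3 peaks.
#' @export
rr_features <- function(r_peaks, fs = 360) {
  if (is.unsorted(r_peaks)) rlang::abort("r_peaks must be sorted")
  n <- length(r_peaks)
  if (n < 3L) {
    rlang::warn("fewer than 3 peaks: no beat has both RR intervals")
    return(tibble::tibble(beat = integer(), pre_RR = double(), post_RR = double()))
  }
  j <- 2:(n - 1L)
  tibble::tibble(
    beat = j,
    pre_RR = (r_peaks[j] - r_peaks[j - 1L]) / fs,
    post_RR = (r_peaks[j + 1L] - r_peaks[j]) / fs
  )
}

#' Assemble the per-beat feature table
#'
#' Runs segmentation, boundary localization and feature computation for one
#' record, joining the morphology features with the RR features (beats
#' lacking either are dropped). When ground-truth annotations are supplied,
#' each beat is labelled by its nearest annotation within the matching
#' tolerance; unmatched beats are dropped.
#'
#' @param record An `ecg_record` (or numeric vector) of *denoised* samples.
#' @param r_peaks Sorted R-peak sample indices.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional annotation tibble (`sample`, `is_pvc`).
#' @param boundary A [boundary_config()].
#' @param tolerance_ms Label-matching tolerance (default 150 ms).
#' @return Tibble with one row per feature-complete beat: `beat`,
#'   `r_global`, the seven features, and `label` (logical `is_pvc`, or `NA`
#'   without annotations).
#' @export
extract_features <- function(record, r_peaks, fs = 360, annotations = NULL,
                             boundary = boundary_config(), tolerance_ms = 150) {
  beats <- segment_beats(record, r_peaks) |>
    locate_qrs(config = boundary) |>
    beat_features(fs = fs)
  rr <- rr_features(r_peaks, fs = fs)
  tbl <- dplyr::inner_join(beats, rr, by = "beat") |>
    dplyr::select(dplyr::all_of(c("beat", "r_global", FEATURE_NAMES)))
  if (!is.null(annotations)) {
    tol <- tolerance_ms / 1000 * fs
    lab <- purrr::map_lgl(tbl$r_global, function(r) {
      d <- abs(annotations$sample - r)
      i <- which.min(d)
      if (length(i) && d[[i]] <= tol) annotations$is_pvc[[i]] else NA
    })
    tbl$label <- lab
    tbl <- dplyr::filter(tbl, !is.na(.data$label))
  } else {
    tbl$label <- NA
  }
  tbl
}

#' Project a feature table onto a subset of features
#'
#' @param features Feature tibble (seven feature columns plus `label`).
#' @param names Character vector, a subset of the seven feature names;
#'   defaults to [default_feature_subset()].
#' @return Tibble with the requested feature columns, in the requested
#'   order, plus `label` if present.
#' @export
select_features <- function(features, names = default_feature_subset()) {
  if (length(names) == 0L) rlang::abort("empty feature subset")
  unknown <- setdiff(names, FEATURE_NAMES)
  if (length(unknown)) {
    rlang::abort(paste0("unknown feature name(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- c(names, intersect("label", colnames(features)))
  dplyr::select(features, dplyr::all_of(keep))
}
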