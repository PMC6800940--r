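#' Confusion counts for binary PVC classification
#'
#' PVC is the positive class: `TP` = true PVC predicted PVC, `TN` = true
#' non-PVC predicted non-PVC, `FP` = non-PVC predicted PVC, `FN` = PVC
#' predicted non-PVC.
#'
#' @param truth,estimate Logical vectors of equal, positive length
#'   (`TRUE` = PVC).
#' @return One-row tibble with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) rlang::abort("length mismatch")
  if (length(truth) == 0L) rlang::abort("empty label vectors")
  truth <- as.logical(truth); estimate <- as.logical(estimate)
  tibble::tibble(
    TP = sum(truth & estimate),
    TN = sum(!truth & !estimate),
    FP = sum(!truth & estimate),
    FN = sum(truth & !estimate)
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, positive predictive value, sensitivity, specificity, and
#' Youden's index `gamma = Se + Sp - 1`. A metric whose denominator is
#' zero is reported as `NA` with a warning, never as 0.
#'
#' @param counts One-row tibble (or list) with `TP`, `TN`, `FP`, `FN`.
#' @return One-row tibble with `Acc`, `PPV`, `Se`, `Sp`, `gamma`
#'   (fractions in `[0, 1]`; `gamma` in `[-1, 1]`).
#' @export
#' @examples
#' classification_metrics(confusion_counts(c(TRUE, FALSE), c(TRUE, FALSE)))
classification_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  stopifnot(length(tp) == 1L, tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) rlang::abort("all confusion counts are zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      rlang::warn(paste0(name, " undefined (zero denominator); reported as NA"))
      return(NA_real_)
    }
    num / den
  }
  se <- ratio(tp, tp + fn, "Se")
  sp <- ratio(tn, tn + fp, "Sp")
  tibble::tibble(
    Acc = (tp + tn) / total,
    PPV = ratio(tp, tp + fp, "PPV"),
    Se = se,
    Sp = sp,
    gamma = se + sp - 1
  )
}

#' Evaluate predicted labels against the truth
#'
#' Convenience wrapper: [confusion_counts()] followed by
#' [classification_metrics()], returned together.
#'
#' @inheritParams confusion_counts
#' @return One-row tibble with the four counts and the five metrics.
#' @export
evaluate_predictions <- function(truth, estimate) {
  counts <- confusion_counts(truth, estimate)
  dplyr::bind_cols(counts, classification_metrics(counts))
}
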