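#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ECG record
#'
#' @param object An `ecg_record`.
#' @param r_peaks Optional detected R-peak indices to mark.
#' @param annotations Optional annotation tibble; PVC beats are marked.
#' @param window Optional two-element sample range to zoom into.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecg_record
#' @export
autoplot.ecg_record <- function(object, r_peaks = NULL, annotations = NULL,
                                window = NULL, ...) {
  df <- tibble::tibble(
    sample = seq_along(object$samples),
    t = (sample - 1) / object$fs,
    mV = object$samples
  )
  if (!is.null(window)) df <- dplyr::filter(df, .data$sample >= window[[1L]],
                                            .data$sample <= window[[2L]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "amplitude (mV)",
      title = sprintf("%s, lead %s", object$record_name, object$lead)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(r_peaks)) {
    pk <- dplyr::filter(df, .data$sample %in% r_peaks)
    p <- p + ggplot2::geom_point(data = pk, colour = "red", size = 1)
  }
  if (!is.null(annotations)) {
    pvc <- dplyr::filter(df, .data$sample %in% annotations$sample[annotations$is_pvc])
    p <- p + ggplot2::geom_point(data = pvc, colour = "blue", shape = 4, size = 2)
  }
  p
}

#' Plot segmented beats with their QRS boundaries
#'
#' @param beats Beat tibble from [locate_qrs()].
#' @param n Number of beats to facet (default 9).
#' @return A ggplot.
#' @export
plot_beats <- function(beats, n = 9L) {
  shown <- utils::head(beats, n)
  df <- shown |>
    dplyr::mutate(local = purrr::map(.data$samples, seq_along)) |>
    tidyr::unnest(c("samples", "local"))
  bounds <- shown |>
    dplyr::select("beat", "qrs_start", "qrs_end") |>
    tidyr::pivot_longer(c("qrs_start", "qrs_end"),
                        names_to = "boundary", values_to = "local")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$local, y = .data$samples)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(
      data = bounds,
      ggplot2::aes(xintercept = .data$local, colour = .data$boundary),
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::facet_wrap(~beat) +
    ggplot2::labs(x = "sample within beat window", y = "amplitude (mV)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted forest's tree-size distribution and OOB error
#'
#' @param object A `pvc_forest`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pvc_forest
#' @export
autoplot.pvc_forest <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$n_leaves)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "leaves per tree", y = "trees",
      title = sprintf("%d trees, OOB error %.4f", object$params$n_trees,
                      object$oob$error)
    ) +
    ggplot2::theme_minimal()
}

#' Plot single-feature importance counts
#'
#' @param importance Tibble from [single_feature_importance()].
#' @return A ggplot.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(
    importance,
    ggplot2::aes(x = stats::reorder(.data$feature, -.data$correct_pvc),
                 y = .data$correct_pvc)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "correctly identified PVC beats") +
    ggplot2::theme_minimal()
}
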