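#' Synthetic ECG generator configuration
#'
#' The generator emulates a two-class (normal vs PVC) single-lead beat
#' stream at 360 Hz. Normal beats are sums of Gaussian bumps (P, Q, R, S,
#' T waves); PVC beats suppress the P wave, widen the QRS by
#' `qrs_width_mult`, scale the R amplitude by `r_amp_mult` (optionally
#' sign-flipped), arrive early (preceding RR shortened by `pre_rr_factor`)
#' and are followed by a compensatory pause that preserves the sum of the
#' two surrounding RR intervals at twice the base RR. White noise,
#' sinusoidal baseline wander and powerline interference can be added.
#'
#' @param fs Sampling rate, Hz.
#' @param n_beats Number of beats to generate.
#' @param duration Optional record length in seconds; when given, the
#'   record is exactly `round(duration * fs)` samples (truncated or
#'   zero-padded) and beats beyond the end are dropped.
#' @param bpm Mean heart rate (beats per minute).
#' @param rr_jitter_sd Standard deviation of the normal RR jitter, seconds.
#' @param pvc_fraction Probability that an eligible beat is a PVC.
#' @param p_suppressed Suppress the P wave of PVC beats.
#' @param qrs_width_mult QRS width multiplier for PVC beats.
#' @param r_amp_mult R amplitude multiplier for PVC beats.
#' @param r_sign_flip Make PVC beats negative-going.
#' @param pre_rr_factor Shortening factor of the PVC's preceding RR.
#' @param noise_sd White noise standard deviation, mV.
#' @param baseline_amp,baseline_freq Baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp,powerline_freq Powerline interference amplitude
#'   (mV) and frequency (50 or 60 Hz).
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 360, n_beats = 300L, duration = NULL, bpm = 60,
                         rr_jitter_sd = 0.02, pvc_fraction = 0.1,
                         p_suppressed = TRUE, qrs_width_mult = 2.5,
                         r_amp_mult = 1.4, r_sign_flip = FALSE,
                         pre_rr_factor = 0.7, noise_sd = 0,
                         baseline_amp = 0, baseline_freq = 0.3,
                         powerline_amp = 0, powerline_freq = 50,
                         seed = 1L) {
  stopifnot(
    fs > 0, n_beats >= 1L, bpm > 0, pvc_fraction >= 0, pvc_fraction <= 1,
    qrs_width_mult > 0, r_amp_mult > 0, pre_rr_factor > 0, noise_sd >= 0
  )
  structure(
    as.list(environment()),
    class = "synth_config"
  )
}

# Gaussian bump centred c seconds from the R time.
.bump <- function(t, centre, amp, width) amp * exp(-((t - centre)^2) / (2 * width^2))

# Default wave parameters (seconds relative to R, amplitudes in mV).
.wave_params <- list(
  P = c(centre = -0.170, amp = 0.12, width = 0.022),
  Q = c(centre = -0.025, amp = -0.12, width = 0.010),
  R = c(centre = 0.000, amp = 1.10, width = 0.011),
  S = c(centre = 0.025, amp = -0.20, width = 0.010),
  T = c(centre = 0.260, amp = 0.30, width = 0.055)
)

#' Generate a synthetic ECG record with ground-truth beat labels
#'
#' @param config A [synth_config()].
#' @return A list with `record` (an `ecg_record`) and `annotations` (a
#'   tibble with `sample`, `symbol`, `aami`, `is_pvc`; `sample` is the true
#'   R location, 1-based).
#' @export
#' @examples
#' sim <- generate_record(synth_config(n_beats = 20, seed = 3))
#' sim$record
generate_record <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  fs <- config$fs
  rr_base <- 60 / config$bpm
  n_beats <- config$n_beats

  # beat schedule: a PVC arrives early and is followed by a compensatory
  # pause; the two intervals around it sum to 2 * rr_base
  r_times <- numeric(n_beats)
  is_pvc <- logical(n_beats)
  t <- 1.0  # lead-in
  for (b in seq_len(n_beats)) {
    if (b == 1L) {
      r_times[[b]] <- t
      next
    }
    prev_pvc <- is_pvc[[b - 1L]]
    pvc_here <- !prev_pvc && b > 2L && b < n_beats &&
      stats::runif(1) < config$pvc_fraction
    rr <- if (pvc_here) {
      config$pre_rr_factor * rr_base
    } else if (prev_pvc) {
      (2 - config$pre_rr_factor) * rr_base  # compensatory pause
    } else {
      rr_base + stats::rnorm(1, sd = config$rr_jitter_sd)
    }
    r_times[[b]] <- r_times[[b - 1L]] + max(rr, 0.3)
    is_pvc[[b]] <- pvc_here
  }

  n_samples <- if (is.null(config$duration)) {
    ceiling((r_times[[n_beats]] + 1.0) * fs)
  } else {
    as.integer(round(config$duration * fs))
  }
  tt <- (seq_len(n_samples) - 1L) / fs
  x <- numeric(n_samples)

  for (b in seq_len(n_beats)) {
    sign_mult <- if (is_pvc[[b]] && config$r_sign_flip) -1 else 1
    for (w in names(.wave_params)) {
      p <- .wave_params[[w]]
      if (is_pvc[[b]]) {
        if (w == "P" && config$p_suppressed) next
        if (w %in% c("Q", "R", "S")) {
          p[["width"]] <- p[["width"]] * config$qrs_width_mult
          p[["amp"]] <- p[["amp"]] * config$r_amp_mult * sign_mult
        }
      }
      # only evaluate near the bump (5 widths) to keep this linear in n
      lo <- max(1L, floor((r_times[[b]] + p[["centre"]] - 5 * p[["width"]]) * fs))
      hi <- min(n_samples, ceiling((r_times[[b]] + p[["centre"]] + 5 * p[["width"]]) * fs))
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + .bump(tt[idx], r_times[[b]] + p[["centre"]],
                               p[["amp"]], p[["width"]])
    }
  }

  if (config$noise_sd > 0) x <- x + stats::rnorm(n_samples, sd = config$noise_sd)
  if (config$baseline_amp > 0) {
    x <- x + config$baseline_amp * sin(2 * pi * config$baseline_freq * tt)
  }
  if (config$powerline_amp > 0) {
    x <- x + config$powerline_amp * sin(2 * pi * config$powerline_freq * tt)
  }

  r_samples <- as.integer(round(r_times * fs)) + 1L
  keep <- r_samples <= n_samples
  ann <- annotation_tibble(r_samples[keep], ifelse(is_pvc[keep], "V", "N"))
  list(
    record = new_ecg_record(x, fs, lead = "MLII", record_name = "synth"),
    annotations = ann
  )
}

# Class-conditional Gaussian parameters of the feature-space generator,
# derived from the morphology knobs: a PVC arrives at pre_rr_factor of the
# base RR, its compensatory pause mirrors that on post_RR, its QRS is
# wider and taller (hence the larger area), and its R amplitude is scaled.
.feature_model <- function(rr_base = 0.8, pre_rr_factor = 0.7,
                           qrs_width_mult = 2.5, r_amp_mult = 1.4) {
  qrs_n <- 0.10; r_n <- 1.10
  list(
    normal = list(
      mean = c(pre_RR = rr_base, post_RR = rr_base,
               QRS_area = qrs_n * r_n, R_amp = r_n),
      sd = c(pre_RR = 0.08, post_RR = 0.09, QRS_area = 0.12, R_amp = 0.20)
    ),
    pvc = list(
      mean = c(pre_RR = pre_rr_factor * rr_base,
               post_RR = (2 - pre_rr_factor) * rr_base,
               QRS_area = qrs_n * qrs_width_mult * r_n * r_amp_mult,
               R_amp = r_n * r_amp_mult),
      sd = c(pre_RR = 0.08, post_RR = 0.09, QRS_area = 0.12, R_amp = 0.20)
    )
  )
}

#' Generate a labelled feature table directly in feature space
#'
#' Draws the four classifier features (`pre_RR`, `post_RR`, `QRS_area`,
#' `R_amp`) from class-conditional diagonal Gaussians whose means follow
#' the PVC morphology: shortened preceding RR (the strongest single
#' discriminator), lengthened following RR, larger QRS area and R
#' amplitude. The class ratio is exact: with ratio `r`, the table holds
#' `round(n / (r + 1))` PVC rows and the rest non-PVC.
#'
#' @param n Total number of beats.
#' @param ratio Majority:minority (non-PVC:PVC) count ratio, e.g. 13, 8,
#'   4, 1.
#' @param seed RNG seed.
#' @param separation Multiplier on the class mean differences; 0 removes
#'   all class signal, 1 (default) is the calibrated morphology.
#' @return Tibble with the four feature columns and logical `label`
#'   (`TRUE` = PVC), minority rows last.
#' @export
#' @examples
#' tbl <- generate_feature_table(n = 7000, ratio = 13, seed = 1)
#' table(tbl$label)
generate_feature_table <- function(n, ratio = 13, seed = 1L, separation = 1) {
  stopifnot(n >= 2L, ratio > 0, separation >= 0)
  n_pvc <- max(1L, round(n / (ratio + 1)))
  n_norm <- n - n_pvc

  model <- .feature_model()
  pvc_mean <- model$normal$mean + separation * (model$pvc$mean - model$normal$mean)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  draw <- function(m, mean, sd) {
    cols <- purrr::map2(mean, sd, ~ stats::rnorm(m, .x, .y))
    tibble::as_tibble(cols)
  }
  norm_tbl <- draw(n_norm, model$normal$mean, model$normal$sd)
  pvc_tbl <- draw(n_pvc, pvc_mean, model$pvc$sd)
  norm_tbl$label <- FALSE
  pvc_tbl$label <- TRUE
  dplyr::bind_rows(norm_tbl, pvc_tbl)
}

#' Log-likelihood-ratio (Bayes) classifier of the feature-space generator
#'
#' The generating model is a pair of diagonal Gaussians, so the Bayes rule
#' is available in closed form; it upper-bounds any classifier trained on
#' data from this generator.
#'
#' @param features Tibble/matrix with the four feature columns.
#' @param prior_pvc Prior probability of the PVC class.
#' @param separation As in [generate_feature_table()].
#' @return Logical vector of Bayes-optimal labels.
#' @export
bayes_rule_labels <- function(features, prior_pvc = 0.5, separation = 1) {
  model <- .feature_model()
  pvc_mean <- model$normal$mean + separation * (model$pvc$mean - model$normal$mean)
  X <- as.matrix(features[, names(model$normal$mean)])
  ll <- function(mean, sd) {
    rowSums(vapply(seq_along(mean), function(j) {
      stats::dnorm(X[, j], mean[[j]], sd[[j]], log = TRUE)
    }, numeric(nrow(X))))
  }
  d <- ll(pvc_mean, model$pvc$sd) - ll(model$normal$mean, model$normal$sd)
  d + log(prior_pvc) - log(1 - prior_pvc) > 0
}

#' Write a record and its annotations as WFDB files
#'
#' Emits `<name>.hea`, `<name>.dat` (format 212, raw value =
#' `round(mV * gain) + baseline`), `<name>.atr` (MIT binary annotations)
#' and `<name>.txt` (text-dialect annotations).
#'
#' @param record An `ecg_record`.
#' @param annotations Annotation tibble (`sample`, `symbol`).
#' @param directory Output directory (created if needed).
#' @param record_name Base name for the files.
#' @param gain ADC units per mV (default 200).
#' @param baseline ADC value of 0 mV (default 1024).
#' @return The record name path prefix, invisibly.
#' @export
write_wfdb <- function(record, annotations, directory,
                       record_name = record$record_name,
                       gain = 200, baseline = 1024) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  raw_vals <- as.integer(round(record$samples * gain)) + as.integer(baseline)
  if (any(raw_vals < -2048L | raw_vals > 2047L)) {
    rlang::abort("samples exceed the 12-bit range at this gain/baseline")
  }
  header <- structure(
    list(
      record_name = record_name, n_signals = 1L, fs = record$fs,
      n_samples = length(raw_vals),
      signals = tibble::tibble(
        file = paste0(record_name, ".dat"), format = 212L,
        gain = gain, baseline = baseline, lead = record$lead
      )
    ),
    class = "wfdb_header"
  )
  prefix <- file.path(directory, record_name)
  write_wfdb_header(header, paste0(prefix, ".hea"))
  writeBin(encode_212(raw_vals), paste0(prefix, ".dat"))
  write_annotations(annotations, paste0(prefix, ".atr"), dialect = "mit")
  write_annotations(annotations, paste0(prefix, ".txt"), dialect = "text")
  invisible(prefix)
}

#' Read a WFDB record and its annotations from a directory
#'
#' @param directory Directory holding `<record_name>.hea/.dat` and an
#'   annotation file.
#' @param record_name Record base name.
#' @param lead Lead to extract (default `"MLII"`).
#' @param ann_dialect `"mit"` (reads `.atr`) or `"text"` (reads `.txt`).
#' @return List with `record` and `annotations`.
#' @export
read_wfdb_record <- function(directory, record_name, lead = "MLII",
                             ann_dialect = c("mit", "text")) {
  ann_dialect <- match.arg(ann_dialect)
  prefix <- file.path(directory, record_name)
  header <- read_wfdb_header(paste0(prefix, ".hea"))
  record <- read_wfdb_signal(paste0(prefix, ".dat"), header, lead = lead)
  ann_path <- paste0(prefix, if (ann_dialect == "mit") ".atr" else ".txt")
  annotations <- read_annotations(ann_path, dialect = ann_dialect)
  list(record = record, annotations = annotations)
}
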