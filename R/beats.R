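#' Population variance of an amplitude window
#'
#' Mean squared deviation from the mean (division by `n`, not `n - 1`),
#' the statistic used by the sliding-window baseline test.
#'
#' @param values Nonempty numeric vector (mV).
#' @return Variance in mV^2.
#' @export
#' @examples
#' beat_variance(c(0, 2)) # 1
beat_variance <- function(values) {
  if (length(values) == 0L) rlang::abort("variance of an empty window is undefined")
  mean((values - mean(values))^2)
}

#' Sliding-window boundary search configuration
#'
#' The QRS onset/offset search slides a 10-sample window split into two
#' 5-sample halves and compares their variances against a flatness
#' tolerance. The tolerance is scale-free: `tau_scale` times the largest
#' half-window variance observed over the beat, floored at `tau_floor`.
#'
#' @param m Window size (two halves of `m/2`); default 10.
#' @param tau Absolute flatness tolerance in mV^2, or `NULL` for the
#'   scale-free default.
#' @param run Length of the strictly monotone run required beyond the
#'   boundary candidate; default 5.
#' @param offset Scan start offset from the window end point; default 4.
#' @param tau_scale,tau_floor Scale factor and floor for the automatic
#'   tolerance.
#' @return A `boundary_config` list.
#' @export
boundary_config <- function(m = 10L, tau = NULL, run = 5L, offset = 4L,
                            tau_scale = 0.02, tau_floor = 1e-6) {
  stopifnot(m %% 2L == 0L, is.null(tau) || tau >= 0, run >= 2L, offset >= 1L)
  structure(
    list(m = as.integer(m), tau = tau, run = as.integer(run),
         offset = as.integer(offset), tau_scale = tau_scale,
         tau_floor = tau_floor),
    class = "boundary_config"
  )
}

# Beat window geometry: 100 samples before the R peak, 150 after, endpoints
# inclusive -> 251 samples; local indices (1-based) P_start = 1, R = 101,
# T_end = 251.
BEAT_PRE <- 100L
BEAT_POST <- 150L
BEAT_LEN <- BEAT_PRE + BEAT_POST + 1L
R_LOCAL <- BEAT_PRE + 1L

#' Segment heartbeats around detected R peaks
#'
#' Extracts the inclusive window `[R - 100, R + 150]` (251 samples) around
#' each peak. Peaks whose window would run off either end of the record are
#' dropped with a message.
#'
#' @param record An `ecg_record`, or a plain numeric vector of samples.
#' @param r_peaks Sorted integer vector of R-peak sample indices (1-based).
#' @return A tibble with one row per kept beat: `beat` (index into
#'   `r_peaks`), `r_global`, `samples` (list-column of length-251 numeric
#'   vectors), `qrs_start`, `qrs_end` (local 1-based indices, `NA` until
#'   localized).
#' @export
segment_beats <- function(record, r_peaks) {
  samples <- if (inherits(record, "ecg_record")) record$samples else record
  if (is.unsorted(r_peaks)) rlang::abort("r_peaks must be sorted")
  n <- length(samples)
  keep <- r_peaks - BEAT_PRE >= 1L & r_peaks + BEAT_POST <= n
  if (any(!keep)) {
    rlang::inform(sprintf(
      "dropping %d beat(s) whose window falls outside the record", sum(!keep)
    ))
  }
  idx <- which(keep)
  tibble::tibble(
    beat = idx,
    r_global = as.integer(r_peaks[idx]),
    samples = purrr::map(r_peaks[idx], function(r) {
      samples[(r - BEAT_PRE):(r + BEAT_POST)]
    }),
    qrs_start = NA_integer_,
    qrs_end = NA_integer_
  )
}

# strictly monotone (all rising or all falling) run?
.strictly_monotone <- function(v) {
  d <- diff(v)
  all(d > 0) || all(d < 0)
}

# automatic flatness tolerance for one beat: tau_scale times the largest
# half-window variance over the full scan range, floored
.auto_tau <- function(beat_samples, config) {
  half <- config$m %/% 2L
  n <- length(beat_samples)
  vars <- vapply(seq_len(n - half + 1L), function(i) {
    beat_variance(beat_samples[i:(i + half - 1L)])
  }, numeric(1))
  max(config$tau_scale * max(vars), config$tau_floor)
}

#' Locate the QRS onset within one beat window
#'
#' Scans forward from the `offset`-th point after P_start. At candidate
#' `X_i` the trailing half-window `[X_i - 4, X_i]` (variance S1) and the
#' leading half-window `[X_i + 1, X_i + 5]` (variance S2) are compared:
#' `X_i` is the onset when S1 < S2, S1 is within the flatness tolerance
#' (a stationary baseline), and the 5 samples after `X_i` are strictly
#' monotone (the QRS take-off).
#'
#' @param beat_samples Numeric vector of length 251 (one beat window).
#' @param config A [boundary_config()].
#' @return Local 1-based index of the onset, or `NA_integer_` when no
#'   index qualifies.
#' @export
find_qrs_start <- function(beat_samples, config = boundary_config()) {
  half <- config$m %/% 2L
  tau <- if (is.null(config$tau)) .auto_tau(beat_samples, config) else config$tau
  # candidate local indices: offset points after P_start, up to R - (m - 2)
  lo <- 1L + config$offset
  hi <- R_LOCAL - (config$m - 2L)
  for (i in lo:hi) {
    s1 <- beat_variance(beat_samples[(i - half + 1L):i])
    s2 <- beat_variance(beat_samples[(i + 1L):(i + half)])
    if (s1 < s2 && s1 <= tau &&
        .strictly_monotone(beat_samples[(i + 1L):(i + config$run)])) {
      return(i)
    }
  }
  NA_integer_
}

#' Locate the QRS offset within one beat window
#'
#' Mirror image of [find_qrs_start()]: scans forward from the R peak within
#' `[R_sample, T_end]` and accepts the first index whose preceding 5
#' samples are strictly monotone (the S-wave return) and whose following
#' half-window `[X_j, X_j + 4]` is a stationary baseline (variance within
#' tolerance and below the variance of the preceding half-window).
#'
#' @inheritParams find_qrs_start
#' @return Local 1-based index of the offset, or `NA_integer_`.
#' @export
find_qrs_end <- function(beat_samples, config = boundary_config()) {
  half <- config$m %/% 2L
  tau <- if (is.null(config$tau)) .auto_tau(beat_samples, config) else config$tau
  lo <- R_LOCAL + half
  hi <- length(beat_samples) - config$offset
  for (j in lo:hi) {
    s_after <- beat_variance(beat_samples[j:(j + half - 1L)])
    s_before <- beat_variance(beat_samples[(j - half):(j - 1L)])
    if (s_after < s_before && s_after <= tau &&
        .strictly_monotone(beat_samples[(j - config$run):(j - 1L)])) {
      return(j)
    }
  }
  NA_integer_
}

#' Localize QRS boundaries for every segmented beat
#'
#' Applies [find_qrs_start()] and [find_qrs_end()] to each beat. Beats for
#' which the search fails fall back to fixed half-widths of 40 samples
#' around the R peak (about 111 ms at 360 Hz) and are flagged.
#'
#' @param beats A beat tibble from [segment_beats()].
#' @param config A [boundary_config()].
#' @return The beat tibble with `qrs_start`, `qrs_end` filled and a logical
#'   `qrs_fallback` column.
#' @export
locate_qrs <- function(beats, config = boundary_config()) {
  starts <- purrr::map_int(beats$samples, find_qrs_start, config = config)
  ends <- purrr::map_int(beats$samples, find_qrs_end, config = config)
  fallback <- is.na(starts) | is.na(ends)
  if (any(fallback)) {
    rlang::inform(sprintf(
      "boundary search fell back to fixed half-widths for %d beat(s)",
      sum(fallback)
    ))
  }
  starts[is.na(starts)] <- R_LOCAL - 40L
  ends[is.na(ends)] <- R_LOCAL + 40L
  beats$qrs_start <- starts
  beats$qrs_end <- ends
  beats$qrs_fallback <- fallback
  beats
}
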