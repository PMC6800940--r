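#' Pan-Tompkins filtering stages
#'
#' Runs the classic pre-decision chain: zero-phase 5-15 Hz band-pass
#' (Butterworth, designed at the given sampling rate), five-point
#' derivative, elementwise squaring, and a trailing moving-window integral
#' of width `round(0.150 * fs)` samples.
#'
#' @param signal Numeric vector of amplitudes.
#' @param fs Sampling rate in Hz.
#' @return A tibble with one row per sample and columns `bandpassed`,
#'   `derivative`, `squared`, `integrated`.
#' @export
pan_tompkins_stages <- function(signal, fs) {
  stopifnot(fs > 0)
  wn <- round(0.150 * fs)
  if (length(signal) < wn) rlang::abort("signal shorter than the integration window")

  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / (fs / 2), type = "pass"), signal)

  # five-point derivative (1/8)(2x[n] + x[n-1] - x[n-3] - 2x[n-4]),
  # delay-compensated by 2 samples
  xpad <- c(rep(bp[[1L]], 4L), bp)
  n <- length(bp)
  der <- (2 * xpad[5:(n + 4)] + xpad[4:(n + 3)] - xpad[2:(n + 1)] -
            2 * xpad[1:n]) / 8
  der <- c(der[3:n], rep(der[[n]], 2L))

  sq <- der^2

  cs <- cumsum(c(rep(sq[[1L]], wn - 1L), sq))
  integrated <- (cs[wn:(n + wn - 1L)] - c(0, cs[seq_len(n - 1L)])) / wn

  tibble::tibble(
    bandpassed = bp, derivative = der, squared = sq, integrated = integrated
  )
}

# local maxima of a series (strictly greater than the previous sample,
# greater-or-equal to the next, to survive flat-topped peaks)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Adaptive dual-threshold decision logic on the integrated signal with a
#' 200 ms refractory period, T-wave rejection by slope comparison for
#' candidates within 360 ms of the previous QRS, and search-back at half
#' threshold when no peak is found within 1.66 times the running RR
#' average. Each accepted decision is refined to the local extremum of the
#' input signal within +/- 75 ms.
#'
#' @param signal Numeric vector (typically the denoised ECG), in mV.
#' @param fs Sampling rate in Hz.
#' @param refractory_ms Minimum spacing between detections (default 200 ms).
#' @param twave_check Apply slope-based T-wave rejection (default TRUE).
#' @return Increasing integer vector of R-peak sample indices (1-based);
#'   may be empty.
#' @export
detect_r_peaks <- function(signal, fs, refractory_ms = 200, twave_check = TRUE) {
  if (!all(is.finite(signal))) rlang::abort("signal contains non-finite samples")
  wn <- round(0.150 * fs)
  if (length(signal) < max(wn, round(2 * fs))) return(integer())
  st <- pan_tompkins_stages(signal, fs)
  mwi <- st$integrated
  der <- st$derivative
  n <- length(mwi)

  refractory <- round(refractory_ms / 1000 * fs)
  twave_win <- round(0.360 * fs)
  delay <- (wn - 1L) %/% 2L  # trailing-integration group delay

  peaks <- .local_maxima(mwi)
  if (length(peaks) == 0L) return(integer())

  # learning phase: 2 s of integrated signal
  learn <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(learn)
  npki <- 0.5 * mean(learn)

  qrs <- integer()        # accepted decision points (integrated-signal index)
  qrs_slope <- numeric()  # max |derivative| near each accepted QRS
  rr_buf <- numeric()

  slope_near <- function(p) {
    lo <- max(1L, p - wn); hi <- min(n, p)
    max(abs(der[lo:hi]))
  }

  accept <- function(p, from_searchback = FALSE) {
    qrs <<- c(qrs, p)
    qrs_slope <<- c(qrs_slope, slope_near(p))
    if (from_searchback) {
      spki <<- 0.25 * mwi[[p]] + 0.75 * spki
    } else {
      spki <<- 0.125 * mwi[[p]] + 0.875 * spki
    }
    if (length(qrs) >= 2L) {
      rr <- diff(utils::tail(qrs, 2L))
      rr_buf <<- utils::tail(c(rr_buf, rr), 8L)
    }
  }

  for (p in peaks) {
    thr1 <- npki + 0.25 * (spki - npki)
    last_q <- if (length(qrs)) qrs[[length(qrs)]] else -Inf
    if (p - last_q < refractory) {
      # a larger integrated peak inside the refractory window supersedes
      # the previous acceptance (e.g. QRS following a P-wave trigger)
      if (length(qrs) && mwi[[p]] > mwi[[last_q]]) {
        qrs[[length(qrs)]] <- p
        qrs_slope[[length(qrs_slope)]] <- slope_near(p)
        spki <- 0.125 * mwi[[p]] + 0.875 * spki
      }
      next
    }

    is_qrs <- mwi[[p]] > thr1
    if (is_qrs && twave_check && length(qrs) &&
        (p - last_q) < twave_win) {
      # candidate inside the T-wave window: require at least half the
      # previous QRS slope
      if (slope_near(p) < 0.5 * qrs_slope[[length(qrs_slope)]]) is_qrs <- FALSE
    }

    if (is_qrs) {
      accept(p)
    } else {
      npki <- 0.125 * mwi[[p]] + 0.875 * npki
      # search-back: no QRS within 166% of the running RR average
      if (length(qrs) && length(rr_buf)) {
        rr_avg <- mean(rr_buf)
        if (p - qrs[[length(qrs)]] > 1.66 * rr_avg) {
          lo <- qrs[[length(qrs)]] + refractory
          cand <- peaks[peaks > lo & peaks < p]
          cand <- cand[mwi[cand] > 0.5 * thr1]
          if (length(cand)) accept(cand[[which.max(mwi[cand])]], from_searchback = TRUE)
        }
      }
    }
  }
  if (length(qrs) == 0L) return(integer())

  # refine: local extremum of the input within +/- 75 ms of the
  # delay-corrected decision point
  half <- round(0.075 * fs)
  refined <- vapply(qrs, function(p) {
    c0 <- max(1L, min(length(signal), p - delay))
    lo <- max(1L, c0 - half); hi <- min(length(signal), c0 + half)
    win <- signal[lo:hi]
    as.integer(lo + which.max(abs(win - stats::median(win))) - 1L)
  }, integer(1))

  ord <- order(refined)
  refined <- refined[ord]
  dup <- duplicated(refined)
  refined <- refined[!dup]
  # enforce the refractory spacing after refinement; of two conflicting
  # detections keep the one with the larger absolute amplitude (rejects
  # P-wave triggers that survived the integrated-signal decision)
  amp <- abs(signal[refined] - stats::median(signal))
  kept <- integer()
  for (i in seq_along(refined)) {
    if (length(kept) && refined[[i]] - refined[[kept[[length(kept)]]]] < refractory) {
      if (amp[[i]] > amp[[kept[[length(kept)]]]]) kept[[length(kept)]] <- i
    } else {
      kept <- c(kept, i)
    }
  }
  as.integer(refined[kept])
}

#' Score detections against reference beat locations
#'
#' Greedy one-to-one nearest matching: candidate pairs within the tolerance
#' are accepted in order of increasing distance (ties toward the earlier
#' reference beat); each reference and each detection is matched at most
#' once. Matched detections are correct, unmatched detections are wrong
#' (false positives), unmatched references are missed (false negatives).
#'
#' @param detected Sorted integer vector of detected R samples.
#' @param reference Sorted integer vector of true R samples.
#' @param fs Sampling rate in Hz.
#' @param tolerance_ms Matching tolerance (default 150 ms).
#' @return One-row tibble: `all`, `correct`, `wrong`, `missed`, `Se`, `PPV`.
#' @export
score_detections <- function(detected, reference, fs, tolerance_ms = 150) {
  if (is.unsorted(detected) || is.unsorted(reference)) {
    rlang::abort("detected and reference sequences must be sorted")
  }
  tol <- tolerance_ms / 1000 * fs
  nd <- length(detected); nr <- length(reference)
  correct <- 0L
  if (nd > 0L && nr > 0L) {
    pairs <- tidyr::expand_grid(d = seq_len(nd), r = seq_len(nr)) |>
      dplyr::mutate(dist = abs(detected[.data$d] - reference[.data$r])) |>
      dplyr::filter(.data$dist <= tol) |>
      dplyr::arrange(.data$dist, .data$r, .data$d)
    used_d <- logical(nd); used_r <- logical(nr)
    for (i in seq_len(nrow(pairs))) {
      di <- pairs$d[[i]]; ri <- pairs$r[[i]]
      if (!used_d[[di]] && !used_r[[ri]]) {
        used_d[[di]] <- TRUE; used_r[[ri]] <- TRUE
        correct <- correct + 1L
      }
    }
  }
  wrong <- nd - correct
  missed <- nr - correct
  tibble::tibble(
    all = nr, correct = correct, wrong = wrong, missed = missed,
    Se = if (nr > 0L) correct / (correct + missed) else NA_real_,
    PPV = if (nd > 0L) correct / (correct + wrong) else NA_real_
  )
}
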