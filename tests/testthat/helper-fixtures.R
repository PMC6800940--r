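# Constructed beat windows with known QRS onset/offset, and independent
# predicate oracles for the sliding-window boundary search.

# Piecewise-linear beat: flat zero baseline, strict rise from `onset + 1`
# to the R peak (local index 101), strict fall to `offset`, flat after,
# with an optional T bump far to the right.
ramp_beat <- function(onset, offset, amp = 1, t_amp = 0.25) {
  x <- numeric(251)
  x[(onset + 1):101] <- seq(0, amp, length.out = 101 - onset + 1)[-1]
  x[101:offset] <- seq(amp, 0, length.out = offset - 100)
  if (t_amp > 0) {
    tc <- min(offset + 60, 235)
    idx <- (offset + 15):251
    x[idx] <- x[idx] + t_amp * exp(-((idx - tc)^2) / (2 * 8^2))
  }
  x
}

# Beat symmetric about the window centre (local index 126): rev(x) == x.
sym_beat <- function(onset, amp = 1) {
  x <- numeric(251)
  x[(onset + 1):126] <- seq(0, amp, length.out = 126 - onset + 1)[-1]
  x[126:(252 - onset)] <- rev(x[onset:126])
  x
}

# Exhaustive re-scan of the QRS-onset predicate: returns ALL qualifying
# local indices (the implementation returns the first).
onset_acceptance_set <- function(b, config = boundary_config()) {
  half <- config$m %/% 2L
  tau <- if (is.null(config$tau)) pvcforest:::.auto_tau(b, config) else config$tau
  hits <- integer()
  for (i in (1L + config$offset):(101L - (config$m - 2L))) {
    s1 <- beat_variance(b[(i - half + 1L):i])
    s2 <- beat_variance(b[(i + 1L):(i + half)])
    d <- diff(b[(i + 1L):(i + config$run)])
    if (s1 < s2 && s1 <= tau && (all(d > 0) || all(d < 0))) hits <- c(hits, i)
  }
  hits
}

# Exhaustive re-scan of the QRS-offset predicate.
offset_acceptance_set <- function(b, config = boundary_config()) {
  half <- config$m %/% 2L
  tau <- if (is.null(config$tau)) pvcforest:::.auto_tau(b, config) else config$tau
  hits <- integer()
  for (j in (101L + half):(length(b) - config$offset)) {
    s_after <- beat_variance(b[j:(j + half - 1L)])
    s_before <- beat_variance(b[(j - half):(j - 1L)])
    d <- diff(b[(j - config$run):(j - 1L)])
    if (s_after < s_before && s_after <= tau && (all(d > 0) || all(d < 0))) {
      hits <- c(hits, j)
    }
  }
  hits
}

# Maximum-cardinality matching between two sorted index sequences under a
# tolerance, by dynamic programming (independent of the greedy matcher).
dp_max_matches <- function(detected, reference, tol) {
  nd <- length(detected); nr <- length(reference)
  f <- matrix(0L, nd + 1L, nr + 1L)
  for (i in nd:1) {
    for (j in nr:1) {
      best <- max(f[i + 1L, j], f[i, j + 1L])
      if (abs(detected[[i]] - reference[[j]]) <= tol) {
        best <- max(best, f[i + 1L, j + 1L] + 1L)
      }
      f[i, j] <- best
    }
  }
  f[1L, 1L]
}

# Exhaustive best-split oracle: every midpoint of every feature, weighted
# Gini computed with plain loops.
oracle_best_split <- function(X, y, min_leaf = 1L) {
  n <- length(y)
  gini <- function(v) {
    if (length(v) == 0L) return(0)
    p <- table(v) / length(v)
    1 - sum(p^2)
  }
  best <- NULL
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1L]) / 2) {
      left <- y[X[, f] <= t]; right <- y[X[, f] > t]
      if (length(left) < min_leaf || length(right) < min_leaf) next
      w <- (length(left) * gini(left) + length(right) * gini(right)) / n
      if (is.null(best) || w < best$impurity - 1e-12) {
        best <- list(feature = f, threshold = t, impurity = w)
      }
    }
  }
  best
}

# Gaussian white noise at a target SNR (dB) relative to a clean signal.
noisy_at_snr <- function(clean, snr_db) {
  sd <- sqrt(mean(clean^2) / 10^(snr_db / 10))
  clean + stats::rnorm(length(clean), sd = sd)
}
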