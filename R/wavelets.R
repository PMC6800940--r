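# Orthogonal Daubechies filter bank and a periodized discrete wavelet
# transform. Scaling (low-pass reconstruction) filters for db2/db4/db8;
# the high-pass analysis filter is the quadrature mirror h[m] = (-1)^m g[L-1-m].
.db_filters <- list(
  db2 = c(
    0.48296291314453416, 0.83651630373780790, 0.22414386804201340,
    -0.12940952255126037
  ),
  db4 = c(
    0.23037781330889650, 0.71484657055291570, 0.63088076792985890,
    -0.02798376941685985, -0.18703481171909309, 0.03084138183556076,
    0.03288301166688520, -0.01059740178506903
  ),
  db8 = c(
    0.05441584224310401, 0.31287159091429995, 0.67563073629728980,
    0.58535468365420670, -0.01582910525634931, -0.28401554296154690,
    0.00047248457391328, 0.12874742662047847, -0.01736930100180755,
    -0.04408825393079475, 0.01398102791739828, 0.00874609404740578,
    -0.00487035299345157, -0.00039174037337695, 0.00067544940645057,
    -0.00011747678412477
  )
)

#' Scaling filter of a Daubechies wavelet
#'
#' @param wavelet One of `"db2"`, `"db4"`, `"db8"`.
#' @return Numeric vector of scaling (low-pass) filter coefficients.
#' @export
wavelet_filter <- function(wavelet) {
  if (!wavelet %in% names(.db_filters)) {
    rlang::abort(paste0(
      "unknown wavelet '", wavelet, "'; available: ",
      paste(names(.db_filters), collapse = ", ")
    ))
  }
  .db_filters[[wavelet]]
}

# circular index helper: ((i - 1) mod n) + 1 for 1-based vectors
.wrap <- function(i, n) ((i - 1L) %% n) + 1L

# One analysis level of the periodized orthonormal DWT. x must have even
# length. Returns list(approx, detail), each length n/2.
dwt_step <- function(x, g) {
  n <- length(x)
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)  # quadrature mirror high-pass
  k <- seq_len(n %/% 2L)
  a <- numeric(n %/% 2L)
  d <- numeric(n %/% 2L)
  for (m in seq_len(L)) {
    xi <- x[.wrap(2L * (k - 1L) + m, n)]
    a <- a + g[[m]] * xi
    d <- d + h[[m]] * xi
  }
  list(approx = a, detail = d)
}

# Multi-level periodized DWT. Length of x must be divisible by 2^levels.
wavelet_decompose <- function(x, wavelet = "db8", levels = 5L) {
  g <- wavelet_filter(wavelet)
  n <- length(x)
  if (n %% 2L^levels != 0L) {
    rlang::abort("signal length must be divisible by 2^levels for the periodized transform")
  }
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- dwt_step(a, g)
    details[[lev]] <- st$detail
    a <- st$approx
  }
  structure(
    list(approx = a, details = details, wavelet = wavelet, levels = levels, n = n),
    class = "wavelet_decomposition"
  )
}

wavelet_reconstruct <- function(decomp) {
  g <- wavelet_filter(decomp$wavelet)
  a <- decomp$approx
  for (lev in rev(seq_len(decomp$levels))) {
    a <- idwt_step(a, decomp$details[[lev]], g)
  }
  a
}

# Inverse of dwt_step (transpose of the orthonormal analysis operator).
# When the filter length exceeds the signal length at a coarse level,
# several taps of one output coefficient collide under wrap-around and plain
# strided subassignment would drop contributions; fall back to explicit loops.
idwt_step <- function(approx, detail, g) {
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  n <- 2L * length(approx)
  x <- numeric(n)
  k <- seq_along(approx)
  if (L <= n) {
    # no two taps of one output coefficient collide: strided accumulation
    for (m in seq_len(L)) {
      j <- .wrap(2L * (k - 1L) + m, n)
      x[j] <- x[j] + approx * g[[m]] + detail * h[[m]]
    }
  } else {
    for (kk in k) {
      for (m in seq_len(L)) {
        j <- .wrap(2L * (kk - 1L) + m, n)
        x[[j]] <- x[[j]] + approx[[kk]] * g[[m]] + detail[[kk]] * h[[m]]
      }
    }
  }
  x
}
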