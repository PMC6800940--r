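#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return The Euclidean distance.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Indices of the k nearest neighbours within the minority set
#'
#' Distances are Euclidean; the query point itself is excluded; distance
#' ties are broken by original row order.
#'
#' @param S Numeric matrix of minority samples (rows).
#' @param i Row index of the query point within `S`.
#' @param k Number of neighbours; must satisfy `k <= nrow(S) - 1`.
#' @return Integer vector of `k` row indices.
#' @export
k_nearest <- function(S, i, k) {
  n <- nrow(S)
  if (k > n - 1L) rlang::abort("k must be at most the minority size minus one")
  d <- sqrt(colSums((t(S) - S[i, ])^2))
  d[[i]] <- Inf
  order(d)[seq_len(k)]  # order() breaks ties by index
}

#' Interpolate a synthetic sample between a point and its neighbour
#'
#' `x_new = x + r * (x' - x)`: every coordinate lies between the
#' corresponding coordinates of `x` and `x'`.
#'
#' @param x,x_prime Numeric vectors of equal length.
#' @param r A draw from Uniform(0, 1).
#' @return The interpolated vector.
#' @export
smote_interpolate <- function(x, x_prime, r) {
  if (length(x) != length(x_prime)) rlang::abort("dimension mismatch")
  x + r * (x_prime - x)
}

#' Balance a labelled feature table with SMOTE
#'
#' Oversamples the minority class toward a target majority:minority ratio.
#' With minority size m and required synthetic count `need`, every minority
#' sample first contributes `N = floor(need / m)` synthetic points (each
#' from a uniformly drawn one of its k nearest minority neighbours, at a
#' Uniform(0,1) interpolation fraction); the residual `need - N * m` points
#' come from uniformly drawn minority base points. Majority rows and
#' original minority rows are untouched; synthetic rows carry the minority
#' label.
#'
#' Draw order (for reproducibility): minority rows in original order, for
#' each of the N rounds a neighbour index then r; then residual base-point
#' indices as one `sample()` call, and per residual point a neighbour index
#' then r.
#'
#' @param data Tibble of numeric feature columns plus a label column with
#'   exactly two distinct values.
#' @param label Name of the label column (default `"label"`).
#' @param ratio Target majority:minority count ratio (default 1, i.e. 1:1).
#' @param k Neighbour count (default 5).
#' @param seed RNG seed.
#' @return The input tibble with synthetic minority rows appended and a
#'   logical `synthetic` column.
#' @export
#' @examples
#' tbl <- generate_feature_table(n = 280, ratio = 13, seed = 1)
#' balanced <- smote_balance(tbl, ratio = 1, seed = 1)
#' table(balanced$label)
smote_balance <- function(data, label = "label", ratio = 1, k = 5L, seed = 1L) {
  stopifnot(label %in% colnames(data), ratio > 0, k >= 1L)
  y <- data[[label]]
  classes <- unique(y)
  if (length(classes) != 2L) rlang::abort("exactly two classes are required")
  counts <- table(match(y, classes))
  minority_class <- classes[[which.min(counts)]]
  feat_cols <- setdiff(colnames(data), label)
  X <- as.matrix(data[y == minority_class, feat_cols])
  m <- nrow(X)
  n_major <- sum(y != minority_class)
  if (k > m - 1L) rlang::abort("k must be at most the minority size minus one")

  target_minority <- round(n_major / ratio)
  need <- max(0L, target_minority - m)
  out <- dplyr::mutate(data, synthetic = FALSE)
  if (need == 0L) return(out)

  N <- need %/% m
  residual <- need - N * m

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  nn <- lapply(seq_len(m), function(i) k_nearest(X, i, k))
  synth <- matrix(0, nrow = need, ncol = ncol(X))
  row_i <- 0L
  if (N > 0L) {
    for (i in seq_len(m)) {
      for (rep in seq_len(N)) {
        nb <- nn[[i]][[sample.int(k, 1L)]]
        r <- stats::runif(1)
        row_i <- row_i + 1L
        synth[row_i, ] <- smote_interpolate(X[i, ], X[nb, ], r)
      }
    }
  }
  if (residual > 0L) {
    base_pts <- sample.int(m, residual, replace = TRUE)
    for (i in base_pts) {
      nb <- nn[[i]][[sample.int(k, 1L)]]
      r <- stats::runif(1)
      row_i <- row_i + 1L
      synth[row_i, ] <- smote_interpolate(X[i, ], X[nb, ], r)
    }
  }

  synth_tbl <- tibble::as_tibble(as.data.frame(synth))
  colnames(synth_tbl) <- feat_cols
  synth_tbl[[label]] <- minority_class
  synth_tbl$synthetic <- TRUE
  dplyr::bind_rows(out, synth_tbl[, colnames(out)])
}
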