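#' Gini impurity of a set of class counts
#'
#' `1 - sum(p_k^2)` over class proportions. Zero for a pure set; 1/2 for
#' two equally frequent classes.
#'
#' @param counts Nonnegative class counts with a positive sum.
#' @return Impurity in `[0, 1 - 1/K]`.
#' @export
#' @examples
#' gini_impurity(c(10, 0))  # 0
#' gini_impurity(c(5, 5))   # 0.5
gini_impurity <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0) {
    rlang::abort("class counts must be nonempty with positive sum")
  }
  if (any(counts < 0)) rlang::abort("class counts must be nonnegative")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Size-weighted Gini index of a partition
#'
#' The impurity of a candidate split: each part contributes its Gini
#' impurity weighted by its share of the samples. Empty parts are skipped.
#'
#' @param labels Vector of class labels.
#' @param groups Vector (same length) assigning each sample to a part.
#' @return Weighted impurity.
#' @export
gini_index <- function(labels, groups) {
  if (length(labels) != length(groups)) rlang::abort("length mismatch")
  n <- length(labels)
  parts <- split(labels, groups)
  sum(vapply(parts, function(part) {
    if (length(part) == 0L) return(0)
    (length(part) / n) * gini_impurity(as.numeric(table(part)))
  }, numeric(1)))
}

# Vectorized best binary threshold split. X: numeric matrix; y: 0/1 integer;
# feats: candidate feature column indices (scanned in ascending order).
# Thresholds are midpoints of consecutive distinct sorted values; both
# children must have at least min_leaf samples. Ties are broken toward the
# lowest feature index, then the lowest threshold. Returns NULL when no
# valid split exists.
best_split_impl <- function(X, y, feats, min_leaf) {
  n <- length(y)
  if (sum(y) == 0L || sum(y) == n) return(NULL)  # pure set: nothing to gain
  best <- NULL
  for (f in sort(feats)) {
    xv <- X[, f]
    o <- order(xv)
    xs <- xv[o]
    c1 <- cumsum(y[o])
    k <- seq_len(n - 1L)
    valid <- (xs[k] < xs[k + 1L]) & (k >= min_leaf) & ((n - k) >= min_leaf)
    if (!any(valid)) next
    k <- k[valid]
    l1 <- c1[k]; ln <- k
    r1 <- c1[[n]] - l1; rn <- n - k
    gl <- 1 - (l1 / ln)^2 - ((ln - l1) / ln)^2
    gr <- 1 - (r1 / rn)^2 - ((rn - r1) / rn)^2
    w <- (ln * gl + rn * gr) / n
    i <- which.min(w)  # first minimum = lowest threshold
    if (is.null(best) || w[[i]] < best$impurity) {
      best <- list(
        feature = f,
        threshold = (xs[[k[[i]]]] + xs[[k[[i]] + 1L]]) / 2,
        impurity = w[[i]]
      )
    }
  }
  best
}

#' Best Gini split of a labelled set
#'
#' Enumerates binary threshold splits at midpoints of consecutive distinct
#' sorted values of each candidate feature and returns the one minimizing
#' the size-weighted child Gini impurity, subject to both children holding
#' at least `min_leaf` samples.
#'
#' @param X Numeric feature matrix (samples by features).
#' @param y Binary label vector (logical or 0/1).
#' @param feats Candidate feature column indices (default: all).
#' @param min_leaf Minimum child size (default 1).
#' @return A list with `feature`, `threshold`, `impurity` and `gain`
#'   (parent impurity minus split impurity), or `NULL` when no valid split
#'   exists.
#' @export
best_split <- function(X, y, feats = seq_len(ncol(X)), min_leaf = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  sp <- best_split_impl(X, y, feats, min_leaf)
  if (is.null(sp)) return(NULL)
  sp$gain <- gini_impurity(c(sum(y == 0L), sum(y == 1L))) - sp$impurity
  sp
}

# Recursive CART growth. Candidate features are re-drawn at every split
# when mtry < p. Leaves predict the majority class; ties go to non-PVC.
grow_tree <- function(X, y, min_split, min_leaf, mtry) {
  p <- ncol(X)
  build <- function(idx, depth) {
    yy <- y[idx]
    n1 <- sum(yy)
    n0 <- length(yy) - n1
    make_leaf <- function() {
      list(leaf = TRUE, counts = c(n0, n1), pred = n1 > n0)
    }
    if (n0 == 0L || n1 == 0L || length(idx) < min_split) return(make_leaf())
    feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    sp <- best_split_impl(X[idx, , drop = FALSE], yy, feats, min_leaf)
    if (is.null(sp)) return(make_leaf())
    go_left <- X[idx, sp$feature] <= sp$threshold
    list(
      leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
      left = build(idx[go_left], depth + 1L),
      right = build(idx[!go_left], depth + 1L)
    )
  }
  build(seq_along(y), 1L)
}

predict_tree <- function(node, X) {
  out <- logical(nrow(X))
  recurse <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$pred
      return(invisible())
    }
    go_left <- X[idx, node$feature] <= node$threshold
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

#' Fit a bagged CART forest
#'
#' Draws `n_trees` bootstrap samples of the training set (n draws with
#' replacement each), grows one CART tree per sample with Gini splitting,
#' and records the in-bag index multiset of every tree so the out-of-bag
#' generalization error can be estimated. Prediction is by majority vote
#' with ties going to the non-PVC class.
#'
#' @param data Tibble of numeric feature columns plus a logical (or 0/1)
#'   label column; `TRUE`/1 is the PVC class.
#' @param label Name of the label column (default `"label"`).
#' @param n_trees Number of trees (default 120).
#' @param min_split Minimum node size to attempt a split (default 100).
#' @param min_leaf Minimum samples per leaf (default 30).
#' @param mtry `"sqrt"` (default) draws `ceiling(sqrt(p))` candidate
#'   features at every split; `"all"` uses every feature (pure bagging).
#' @param seed RNG seed; fits are reproducible under a fixed seed.
#' @return A `pvc_forest` object.
#' @export
#' @examples
#' tbl <- generate_feature_table(n = 700, ratio = 1, seed = 2)
#' fit <- pvc_forest(tbl, n_trees = 20, seed = 2)
#' glance(fit)
pvc_forest <- function(data, label = "label", n_trees = 120L,
                       min_split = 100L, min_leaf = 30L,
                       mtry = c("sqrt", "all"), seed = 1L) {
  mtry <- match.arg(mtry)
  stopifnot(n_trees >= 1L, min_split >= 2L, min_leaf >= 1L)
  if (!label %in% colnames(data)) rlang::abort(paste0("no label column '", label, "'"))
  y <- as.logical(data[[label]])
  if (anyNA(y)) rlang::abort("labels contain NA")
  if (length(unique(y)) < 2L) rlang::abort("training data must contain both classes")
  feat_names <- setdiff(colnames(data), c(label, "synthetic"))
  X <- as.matrix(data[, feat_names])
  if (!is.numeric(X)) rlang::abort("feature columns must be numeric")
  n <- nrow(X)
  p <- ncol(X)
  m_feats <- if (mtry == "sqrt") max(1L, ceiling(sqrt(p))) else p

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  trees <- vector("list", n_trees)
  bags <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    bag <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(
      X[bag, , drop = FALSE], as.integer(y[bag]),
      min_split = min_split, min_leaf = min_leaf, mtry = m_feats
    )
    bags[[t]] <- bag
  }

  forest <- structure(
    list(
      trees = trees, bags = bags, features = feat_names,
      params = list(
        n_trees = n_trees, min_split = min_split, min_leaf = min_leaf,
        mtry = mtry, seed = seed
      ),
      n_train = n, X = X, y = y
    ),
    class = "pvc_forest"
  )
  forest$oob <- oob_error(forest)
  forest
}

#' @export
print.pvc_forest <- function(x, ...) {
  cat(sprintf(
    "<pvc_forest> %d trees on %d samples x %d features (%s)\n",
    x$params$n_trees, x$n_train, length(x$features),
    paste(x$features, collapse = ", ")
  ))
  if (!is.null(x$oob)) {
    cat(sprintf("  OOB error: %.4f (%d/%d samples with OOB votes)\n",
                x$oob$error, x$oob$n_voted, x$n_train))
  }
  invisible(x)
}

.forest_matrix <- function(forest, newdata) {
  if (is.matrix(newdata)) {
    X <- newdata
    if (!is.null(colnames(X))) X <- X[, forest$features, drop = FALSE]
  } else {
    missing <- setdiff(forest$features, colnames(newdata))
    if (length(missing)) {
      rlang::abort(paste0("newdata lacks feature(s): ", paste(missing, collapse = ", ")))
    }
    X <- as.matrix(newdata[, forest$features])
  }
  if (ncol(X) != length(forest$features)) rlang::abort("feature dimension mismatch")
  X
}

#' Predict with a fitted forest
#'
#' @param object A `pvc_forest`.
#' @param newdata Tibble or matrix with the training feature columns.
#' @param type `"class"` for the majority-vote label (ties to non-PVC) or
#'   `"prob"` for the fraction of trees voting PVC.
#' @param ... Unused.
#' @return Logical vector (`"class"`) or numeric vote fractions (`"prob"`).
#' @export
predict.pvc_forest <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- .forest_matrix(object, newdata)
  votes <- numeric(nrow(X))
  for (tree in object$trees) votes <- votes + predict_tree(tree, X)
  frac <- votes / length(object$trees)
  if (type == "prob") frac else frac > 0.5
}

#' Out-of-bag predictions
#'
#' Each training sample is voted on only by the trees whose bootstrap
#' sample did not contain it; ties go to non-PVC.
#'
#' @param forest A fitted `pvc_forest`.
#' @return Tibble with one row per training sample: `index`,
#'   `n_oob_trees`, `oob_pred` (`NA` when no tree left the sample out).
#' @export
oob_predictions <- function(forest) {
  n <- forest$n_train
  votes <- numeric(n)
  n_trees <- integer(n)
  for (t in seq_along(forest$trees)) {
    oob_idx <- setdiff(seq_len(n), forest$bags[[t]])
    if (length(oob_idx) == 0L) next
    pred <- predict_tree(forest$trees[[t]], forest$X[oob_idx, , drop = FALSE])
    votes[oob_idx] <- votes[oob_idx] + pred
    n_trees[oob_idx] <- n_trees[oob_idx] + 1L
  }
  tibble::tibble(
    index = seq_len(n),
    n_oob_trees = n_trees,
    oob_pred = dplyr::if_else(n_trees > 0L, votes > n_trees / 2, NA)
  )
}

#' Out-of-bag error estimate
#'
#' Fraction of training samples misclassified by their out-of-bag votes,
#' among samples with at least one out-of-bag tree.
#'
#' @param forest A fitted `pvc_forest`.
#' @return List with `error`, `n_voted` and `n_excluded`.
#' @export
oob_error <- function(forest) {
  op <- oob_predictions(forest)
  voted <- op$n_oob_trees > 0L
  list(
    error = mean(op$oob_pred[voted] != forest$y[voted]),
    n_voted = sum(voted),
    n_excluded = sum(!voted)
  )
}

#' Single-feature importance by PVC recall
#'
#' For each feature alone, fits a forest on the training set and counts the
#' PVC beats of the evaluation set it identifies correctly; features are
#' ranked by that count, descending.
#'
#' @param train,eval Labelled feature tibbles.
#' @param label Label column name.
#' @param ... Passed to [pvc_forest()] (e.g. `n_trees`, `seed`).
#' @return Tibble with `feature`, `correct_pvc`, `rank`.
#' @export
single_feature_importance <- function(train, eval, label = "label", ...) {
  feat_names <- setdiff(colnames(train), c(label, "synthetic"))
  if (length(feat_names) < 2L) rlang::abort("need at least two features to rank")
  truth <- as.logical(eval[[label]])
  counts <- purrr::map_int(feat_names, function(f) {
    fit <- pvc_forest(train[, c(f, label)], label = label, mtry = "all", ...)
    pred <- predict(fit, eval[, f, drop = FALSE])
    sum(pred & truth)
  })
  tibble::tibble(feature = feat_names, correct_pvc = counts) |>
    dplyr::arrange(dplyr::desc(.data$correct_pvc)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

# ---------------------------------------------------------------------------
# broom-style methods

tree_stats <- function(node, depth = 1L) {
  if (isTRUE(node$leaf)) {
    return(c(nodes = 1L, leaves = 1L, depth = depth))
  }
  l <- tree_stats(node$left, depth + 1L)
  r <- tree_stats(node$right, depth + 1L)
  c(
    nodes = 1L + l[["nodes"]] + r[["nodes"]],
    leaves = l[["leaves"]] + r[["leaves"]],
    depth = max(l[["depth"]], r[["depth"]])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-tree summary of a fitted forest
#'
#' @param x A `pvc_forest`.
#' @param ... Unused.
#' @return Tibble with one row per tree: `tree`, `n_nodes`, `n_leaves`,
#'   `depth`, `n_unique_inbag`.
#' @method tidy pvc_forest
#' @export
tidy.pvc_forest <- function(x, ...) {
  stats <- purrr::map(x$trees, tree_stats)
  tibble::tibble(
    tree = seq_along(x$trees),
    n_nodes = purrr::map_int(stats, ~ .x[["nodes"]]),
    n_leaves = purrr::map_int(stats, ~ .x[["leaves"]]),
    depth = purrr::map_int(stats, ~ .x[["depth"]]),
    n_unique_inbag = purrr::map_int(x$bags, ~ length(unique(.x)))
  )
}

#' One-row summary of a fitted forest
#'
#' @param x A `pvc_forest`.
#' @param ... Unused.
#' @return One-row tibble: training size, parameters, OOB error and
#'   coverage.
#' @method glance pvc_forest
#' @export
glance.pvc_forest <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_features = length(x$features),
    n_trees = x$params$n_trees,
    min_split = x$params$min_split,
    min_leaf = x$params$min_leaf,
    mtry = x$params$mtry,
    oob_error = x$oob$error,
    oob_coverage = x$oob$n_voted / x$n_train
  )
}

# ---------------------------------------------------------------------------
# JSON serialization

node_to_list <- function(node) {
  if (isTRUE(node$leaf)) {
    list(leaf = TRUE, counts = as.integer(node$counts), pred = node$pred)
  } else {
    list(
      leaf = FALSE, feature = node$feature, threshold = node$threshold,
      left = node_to_list(node$left), right = node_to_list(node$right)
    )
  }
}

node_from_list <- function(lst) {
  if (isTRUE(lst$leaf)) {
    list(leaf = TRUE, counts = as.integer(unlist(lst$counts)),
         pred = as.logical(lst$pred))
  } else {
    list(
      leaf = FALSE, feature = as.integer(lst$feature),
      threshold = as.numeric(lst$threshold),
      left = node_from_list(lst$left), right = node_from_list(lst$right)
    )
  }
}

#' Serialize a fitted forest to JSON
#'
#' Writes parameters, feature names, per-tree in-bag multisets and the
#' nested tree nodes. Training data are not serialized, so a reloaded
#' forest predicts but does not recompute OOB estimates.
#'
#' @param forest A `pvc_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
forest_to_json <- function(forest, path) {
  obj <- list(
    params = forest$params,
    features = forest$features,
    n_train = forest$n_train,
    oob_error = forest$oob$error,
    bags = forest$bags,
    trees = purrr::map(forest$trees, node_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a forest serialized with [forest_to_json()]
#'
#' @param path Path to the JSON file.
#' @return A `pvc_forest` (without training data).
#' @export
forest_from_json <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(
    list(
      trees = purrr::map(obj$trees, node_from_list),
      bags = purrr::map(obj$bags, ~ as.integer(unlist(.x))),
      features = as.character(unlist(obj$features)),
      params = obj$params,
      n_train = obj$n_train,
      X = NULL, y = NULL,
      oob = list(error = obj$oob_error, n_voted = NA_integer_,
                 n_excluded = NA_integer_)
    ),
    class = "pvc_forest"
  )
}
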