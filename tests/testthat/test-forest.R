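test_that("Gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(7, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(numeric()), "nonempty")
  expect_error(gini_impurity(c(0, 0)), "positive sum")
})

test_that("the weighted Gini index of a partition is correct", {
  y <- c(0, 0, 1, 1)
  expect_equal(gini_index(y, c(1, 1, 2, 2)), 0)      # pure parts
  expect_equal(gini_index(y, rep(1, 4)), gini_impurity(c(2, 2)))
  set.seed(32)
  yy <- sample(0:1, 30, replace = TRUE)
  gg <- sample(1:2, 30, replace = TRUE)
  manual <- 0
  for (g in 1:2) {
    part <- yy[gg == g]
    p <- table(part) / length(part)
    manual <- manual + length(part) / 30 * (1 - sum(p^2))
  }
  expect_equal(gini_index(yy, gg), manual, tolerance = 1e-12)
})

test_that("a separable 1-D set splits at the midpoint with pure children", {
  X <- matrix(c(1, 2, 8, 9), ncol = 1)
  y <- c(0L, 0L, 1L, 1L)
  sp <- best_split(X, y, min_leaf = 1L)
  expect_equal(sp$threshold, 5)
  expect_equal(sp$impurity, 0)
  expect_equal(sp$gain, 0.5)
})

test_that("pure sets and constant features yield no split", {
  expect_null(best_split(matrix(rnorm(10)), rep(1L, 10)))
  expect_null(best_split(matrix(rep(3, 10)), rep(c(0L, 1L), 5)))
})

test_that("best_split matches exhaustive search on random instances", {
  set.seed(33)
  for (trial in 1:200) {
    n <- sample(4:50, 1L)
    p <- sample(1:3, 1L)
    X <- matrix(round(rnorm(n * p), sample(0:2, 1L)), ncol = p)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
    min_leaf <- sample(1:3, 1L)
    got <- best_split(X, y, min_leaf = min_leaf)
    want <- oracle_best_split(X, y, min_leaf = min_leaf)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$impurity, want$impurity, tolerance = 1e-12)
      # the returned pair must achieve the oracle minimum
      left <- y[X[, got$feature] <= got$threshold]
      right <- y[X[, got$feature] > got$threshold]
      g <- function(v) { p <- table(v) / length(v); 1 - sum(p^2) }
      w <- (length(left) * g(left) + length(right) * g(right)) / n
      expect_equal(w, want$impurity, tolerance = 1e-12)
    }
  }
})

test_that("split selection is deterministic under ties", {
  X <- cbind(c(0, 0, 1, 1), c(0, 0, 1, 1))  # identical features tie exactly
  y <- c(0L, 0L, 1L, 1L)
  sp <- best_split(X, y, min_leaf = 1L)
  expect_equal(sp$feature, 1L)  # lowest feature index wins
})

test_that("tree growth stops on purity and size, conserving counts", {
  X <- matrix(rnorm(20), ncol = 2)
  pure <- pvcforest:::grow_tree(X, rep(0L, 10), min_split = 2L,
                                min_leaf = 1L, mtry = 2L)
  expect_true(pure$leaf)

  small <- pvcforest:::grow_tree(X, rep(c(0L, 1L), 5), min_split = 50L,
                                 min_leaf = 1L, mtry = 2L)
  expect_true(small$leaf)

  set.seed(34)
  n <- 300L
  X2 <- matrix(rnorm(n * 2), ncol = 2)
  y2 <- as.integer(X2[, 1] + rnorm(n, sd = 0.5) > 0)
  tree <- pvcforest:::grow_tree(X2, y2, min_split = 20L, min_leaf = 5L, mtry = 2L)
  leaf_total <- function(node) {
    if (isTRUE(node$leaf)) return(sum(node$counts))
    leaf_total(node$left) + leaf_total(node$right)
  }
  expect_equal(leaf_total(tree), n)
  min_leaf_size <- function(node) {
    if (isTRUE(node$leaf)) return(sum(node$counts))
    min(min_leaf_size(node$left), min_leaf_size(node$right))
  }
  expect_gte(min_leaf_size(tree), 5L)
})

test_that("a single-tree forest predicts exactly like its tree", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 35)
  f <- pvc_forest(tbl, n_trees = 1L, min_split = 50L, min_leaf = 10L, seed = 3)
  newdata <- generate_feature_table(n = 100, ratio = 2, seed = 36)
  X <- as.matrix(newdata[, f$features])
  expect_equal(predict(f, newdata),
               pvcforest:::predict_tree(f$trees[[1L]], X))
})

test_that("fitting is reproducible under a fixed seed", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 37)
  f1 <- pvc_forest(tbl, n_trees = 15L, seed = 9)
  f2 <- pvc_forest(tbl, n_trees = 15L, seed = 9)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$bags, f2$bags)
})

test_that("the unique in-bag fraction matches bootstrap theory", {
  tbl <- generate_feature_table(n = 5000, ratio = 2, seed = 38)
  f <- pvc_forest(tbl, n_trees = 30L, seed = 10)
  frac <- mean(vapply(f$bags, function(b) length(unique(b)) / 5000, numeric(1)))
  expect_lt(abs(frac - (1 - exp(-1))), 0.02)
})

test_that("votes aggregate as documented, with ties to non-PVC", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 39)
  f <- pvc_forest(tbl, n_trees = 11L, min_split = 50L, min_leaf = 10L, seed = 4)
  newdata <- generate_feature_table(n = 10, ratio = 2, seed = 40)
  X <- as.matrix(newdata[, f$features])
  tally <- rowMeans(vapply(f$trees, function(tr) {
    pvcforest:::predict_tree(tr, X)
  }, logical(10)))
  expect_equal(predict(f, newdata, type = "prob"), tally)
  expect_equal(predict(f, newdata), tally > 0.5)

  # hand-built two-tree forest with a split vote
  leaf <- function(pred) list(leaf = TRUE, counts = c(1L, 1L), pred = pred)
  tie <- f
  tie$trees <- list(leaf(TRUE), leaf(FALSE))
  tie$params$n_trees <- 2L
  expect_false(predict(tie, newdata)[[1L]])
  expect_equal(predict(tie, newdata, type = "prob")[[1L]], 0.5)
})

test_that("prediction rejects mismatched feature dimensions", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 41)
  f <- pvc_forest(tbl, n_trees = 5L, seed = 1)
  expect_error(predict(f, tbl[, c("pre_RR", "label")]), "lacks feature")
})

test_that("OOB votes agree with a brute-force membership recomputation", {
  tbl <- generate_feature_table(n = 400, ratio = 2, seed = 42)
  f <- pvc_forest(tbl, n_trees = 25L, min_split = 50L, min_leaf = 10L, seed = 5)
  op <- oob_predictions(f)
  votes <- numeric(400); ntr <- integer(400)
  for (t in seq_along(f$trees)) {
    for (i in seq_len(400)) {
      if (!(i %in% f$bags[[t]])) {
        votes[[i]] <- votes[[i]] +
          pvcforest:::predict_tree(f$trees[[t]], f$X[i, , drop = FALSE])
        ntr[[i]] <- ntr[[i]] + 1L
      }
    }
  }
  expect_equal(op$n_oob_trees, ntr)
  expect_equal(op$oob_pred, ifelse(ntr > 0L, votes > ntr / 2, NA))
})

test_that("OOB error is near zero on well-separated classes", {
  tbl <- generate_feature_table(n = 2000, ratio = 1, seed = 43)
  f <- pvc_forest(tbl, n_trees = 60L, seed = 6)
  expect_lt(f$oob$error, 0.03)
})

test_that("single-feature importance finds a perfectly separating feature", {
  set.seed(44)
  n <- 400L
  train <- tibble::tibble(
    junk = rnorm(n),
    perfect = c(rnorm(n / 2, -4, 0.3), rnorm(n / 2, 4, 0.3)),
    label = rep(c(FALSE, TRUE), each = n / 2)
  )
  eval_tbl <- train[sample.int(n), ]
  imp <- single_feature_importance(train, eval_tbl, n_trees = 10L,
                                   min_split = 20L, min_leaf = 5L, seed = 7)
  expect_equal(imp$feature[[1L]], "perfect")
  expect_equal(imp$rank[imp$feature == "perfect"], 1L)
})

test_that("preceding RR dominates the generator's feature ranking", {
  train <- generate_feature_table(n = 3000, ratio = 4, seed = 45)
  eval_tbl <- generate_feature_table(n = 1500, ratio = 4, seed = 46)
  imp <- single_feature_importance(train, eval_tbl, n_trees = 30L, seed = 8)
  expect_equal(imp$feature[[1L]], "pre_RR")
})

test_that("a forest survives a JSON round trip", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 47)
  f <- pvc_forest(tbl, n_trees = 8L, min_split = 50L, min_leaf = 10L, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  forest_to_json(f, path)
  g <- forest_from_json(path)
  newdata <- generate_feature_table(n = 200, ratio = 2, seed = 48)
  expect_identical(predict(g, newdata), predict(f, newdata))
  expect_equal(g$oob$error, f$oob$error)
})

test_that("tidy and glance summarise the ensemble", {
  tbl <- generate_feature_table(n = 600, ratio = 2, seed = 49)
  f <- pvc_forest(tbl, n_trees = 7L, seed = 3)
  td <- tidy(f)
  expect_equal(nrow(td), 7L)
  expect_true(all(td$n_leaves >= 1L))
  expect_true(all(td$n_nodes == 2L * td$n_leaves - 1L))
  gl <- glance(f)
  expect_equal(gl$n_trees, 7L)
  expect_true(gl$oob_error >= 0 && gl$oob_error <= 1)
})
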