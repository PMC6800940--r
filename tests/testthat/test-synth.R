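test_that("a zero PVC fraction produces only normal beats", {
  sim <- generate_record(synth_config(n_beats = 40L, pvc_fraction = 0, seed = 1))
  expect_false(any(sim$annotations$is_pvc))
  expect_true(all(sim$annotations$symbol == "N"))
})

test_that("an explicit duration fixes the sample count exactly", {
  sim <- generate_record(synth_config(n_beats = 20L, duration = 30, seed = 2))
  expect_length(sim$record$samples, 30L * 360L)
})

test_that("the PVC count falls in the binomial 99% interval", {
  sim <- generate_record(synth_config(n_beats = 300L, pvc_fraction = 0.1, seed = 3))
  k <- sum(sim$annotations$is_pvc)
  bounds <- stats::qbinom(c(0.005, 0.995), 300L, 0.1)
  expect_gte(k, bounds[[1L]])
  expect_lte(k, bounds[[2L]])
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_beats = 50L, pvc_fraction = 0.2, noise_sd = 0.05, seed = 4)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$annotations, b$annotations)
  expect_identical(generate_feature_table(500, ratio = 4, seed = 5),
                   generate_feature_table(500, ratio = 4, seed = 5))
})

test_that("PVC beats arrive early relative to the base RR", {
  cfg <- synth_config(n_beats = 200L, pvc_fraction = 0.15, seed = 6)
  sim <- generate_record(cfg)
  ann <- sim$annotations
  rr_into <- diff(ann$sample) / 360
  pvc_pos <- which(ann$is_pvc)
  pvc_pos <- pvc_pos[pvc_pos > 1L]
  rr_base <- 60 / cfg$bpm
  expect_true(all(rr_into[pvc_pos - 1L] < rr_base))
  # compensatory pause: the two intervals around a PVC sum to ~2 RR
  interior <- pvc_pos[pvc_pos < nrow(ann)]
  sums <- rr_into[interior - 1L] + rr_into[interior]
  expect_true(all(abs(sums - 2 * rr_base) < 0.02))
})

test_that("the feature-table class ratio is exact", {
  tbl <- generate_feature_table(n = 7000, ratio = 13, seed = 7)
  expect_equal(sum(tbl$label), 500L)
  expect_equal(sum(!tbl$label), 6500L)
  tbl2 <- generate_feature_table(n = 280, ratio = 1, seed = 8)
  expect_equal(sum(tbl2$label), 140L)
})

test_that("zero class separation leaves the forest at the majority prior", {
  tbl <- generate_feature_table(n = 2000, ratio = 4, seed = 9, separation = 0)
  test_tbl <- generate_feature_table(n = 1000, ratio = 4, seed = 10, separation = 0)
  f <- pvc_forest(tbl, n_trees = 30L, seed = 11)
  acc <- mean(predict(f, test_tbl) == test_tbl$label)
  expect_lt(abs(acc - 0.8), 0.05)  # majority prior = 4/5
})

test_that("the closed-form Bayes rule upper-bounds the forest", {
  train <- generate_feature_table(n = 4000, ratio = 4, seed = 12)
  test_tbl <- generate_feature_table(n = 4000, ratio = 4, seed = 13)
  f <- pvc_forest(train, n_trees = 60L, seed = 14)
  acc_forest <- mean(predict(f, test_tbl) == test_tbl$label)
  acc_bayes <- mean(bayes_rule_labels(test_tbl, prior_pvc = 0.2) == test_tbl$label)
  expect_gte(acc_bayes + 0.005, acc_forest)
  expect_gt(acc_bayes, 0.95)
})

test_that("a beat-free record still writes valid files", {
  rec <- pvcforest:::new_ecg_record(rep(0.5, 720), 360)
  ann <- pvcforest:::annotation_tibble(integer(), character())
  dir <- withr::local_tempdir()
  write_wfdb(rec, ann, dir, "empty")
  back <- read_wfdb_record(dir, "empty")
  expect_equal(nrow(back$annotations), 0L)
  expect_equal(back$record$samples, rep(0.5, 720), tolerance = 1 / 200)
})

test_that("the ADC scaling follows raw = mV * gain + baseline", {
  rec <- pvcforest:::new_ecg_record(c(1, 0, -1), 360)
  ann <- pvcforest:::annotation_tibble(integer(), character())
  dir <- withr::local_tempdir()
  write_wfdb(rec, ann, dir, "adc", gain = 200, baseline = 1024)
  bytes <- readBin(file.path(dir, "adc.dat"), "raw", n = 6L)
  raw_vals <- pvcforest:::decode_212(bytes, 3L)
  expect_equal(raw_vals, c(1224L, 1024L, 824L))
})
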