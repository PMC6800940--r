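test_that("beat windows cover the inclusive 251-sample span around R", {
  x <- seq_len(1000) / 1000
  beats <- segment_beats(x, c(500L))
  expect_equal(beats$samples[[1L]], x[400:650])
  expect_length(beats$samples[[1L]], 251L)
})

test_that("peaks whose window leaves the record are dropped", {
  x <- rnorm(1000)
  expect_message(beats <- segment_beats(x, c(50L, 500L, 990L)), "dropping 2")
  expect_equal(beats$r_global, 500L)
})

test_that("every interior peak yields one beat", {
  sim <- generate_record(synth_config(n_beats = 50L, seed = 2))
  peaks <- sim$annotations$sample
  beats <- segment_beats(sim$record, peaks)
  expect_equal(nrow(beats), length(peaks))
})

test_that("the window variance is the population variance", {
  expect_equal(beat_variance(c(1, 1, 1)), 0)
  expect_equal(beat_variance(c(0, 2)), 1)
  set.seed(14)
  v <- rnorm(10)
  expect_equal(beat_variance(v), sum((v - sum(v) / 10)^2) / 10, tolerance = 1e-12)
  expect_error(beat_variance(numeric()), "empty")
})

test_that("the onset localizer finds the foot of a ramp", {
  set.seed(15)
  for (trial in 1:20) {
    onset <- sample(60:85, 1L)
    offset <- sample(115:140, 1L)
    b <- ramp_beat(onset, offset, amp = stats::runif(1, 0.5, 1.5))
    found <- find_qrs_start(b)
    expect_false(is.na(found))
    expect_lte(abs(found - onset), 2L)
  }
})

test_that("the offset localizer finds the end of the descent", {
  set.seed(16)
  for (trial in 1:20) {
    onset <- sample(60:85, 1L)
    offset <- sample(115:140, 1L)
    b <- ramp_beat(onset, offset, amp = stats::runif(1, 0.5, 1.5))
    found <- find_qrs_end(b)
    expect_false(is.na(found))
    expect_lte(abs(found - offset), 2L)
  }
})

test_that("flat or monotone-free beats yield not-found", {
  expect_true(is.na(find_qrs_start(numeric(251))))
  expect_true(is.na(find_qrs_end(numeric(251))))
  # rise to R, then perfectly flat: no descent, no offset
  b <- c(numeric(70), seq(0, 1, length.out = 31), rep(1, 150))
  expect_true(is.na(find_qrs_end(b)))
})

test_that("the implementation agrees with an exhaustive predicate re-scan", {
  set.seed(17)
  for (trial in 1:100) {
    b <- ramp_beat(sample(60:85, 1L), sample(115:140, 1L),
                   amp = stats::runif(1, 0.3, 2),
                   t_amp = stats::runif(1, 0, 0.4))
    sset <- onset_acceptance_set(b)
    eset <- offset_acceptance_set(b)
    expect_equal(find_qrs_start(b),
                 if (length(sset)) sset[[1L]] else NA_integer_)
    expect_equal(find_qrs_end(b),
                 if (length(eset)) eset[[1L]] else NA_integer_)
  }
})

test_that("onset and offset predicates are exact mirrors of each other", {
  set.seed(18)
  for (trial in 1:25) {
    b <- sym_beat(sample(60:90, 1L), amp = stats::runif(1, 0.5, 1.5))
    expect_identical(b, rev(b))
    eset <- offset_acceptance_set(b)
    sset <- onset_acceptance_set(rev(b))
    # mirrored acceptance sets coincide on the shared scan range
    mirrored <- sort(252L - sset)
    shared <- mirrored[mirrored >= 106L]
    expect_identical(sort(eset[eset >= min(shared)]), shared)
    if (length(eset) == 1L && length(sset) == 1L) {
      expect_equal(find_qrs_end(b), 252L - find_qrs_start(rev(b)))
    }
  }
})

test_that("boundary search is invariant to amplitude translation", {
  set.seed(19)
  b <- ramp_beat(70, 130, amp = 1.2)
  for (shift in c(-3, 0.5, 10)) {
    expect_identical(find_qrs_start(b + shift), find_qrs_start(b))
    expect_identical(find_qrs_end(b + shift), find_qrs_end(b))
  }
})

test_that("localized boundaries straddle the R sample", {
  sim <- generate_record(synth_config(n_beats = 60L, pvc_fraction = 0.15, seed = 20))
  x <- denoise_signal(sim$record$samples, denoise_config())
  beats <- locate_qrs(segment_beats(x, sim$annotations$sample))
  expect_true(all(beats$qrs_start < 101L))
  expect_true(all(beats$qrs_end > 101L))
})

test_that("median localization error is within 3 samples on known beats", {
  set.seed(21)
  errs <- t(vapply(1:100, function(i) {
    onset <- sample(60:85, 1L)
    offset <- sample(115:140, 1L)
    b <- ramp_beat(onset, offset, amp = stats::runif(1, 0.4, 1.6))
    c(abs(find_qrs_start(b) - onset), abs(find_qrs_end(b) - offset))
  }, numeric(2)))
  expect_lte(stats::median(errs[, 1L]), 3)
  expect_lte(stats::median(errs[, 2L]), 3)
})
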