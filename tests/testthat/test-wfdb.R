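test_that("header parsing extracts the record geometry", {
  path <- withr::local_tempfile(fileext = ".hea")
  writeLines(c(
    "100 2 360 650000",
    "100.dat 212 200(1024)/mV 11 1024 995 0 0 MLII",
    "100.dat 212 200(1024)/mV 11 1024 1011 0 0 V5"
  ), path)
  h <- read_wfdb_header(path)
  expect_equal(h$n_signals, 2L)
  expect_equal(h$fs, 360)
  expect_equal(h$n_samples, 650000)
  expect_equal(h$signals$lead, c("MLII", "V5"))
  expect_equal(h$signals$gain, c(200, 200))
  expect_equal(h$signals$baseline, c(1024, 1024))
})

test_that("a minimal header round-trips through the writer", {
  path <- withr::local_tempfile(fileext = ".hea")
  writeLines(c("s 1 360 10", "s.dat 212 200(0)/mV 12 0 0 0 0 MLII"), path)
  h <- read_wfdb_header(path)
  out <- withr::local_tempfile(fileext = ".hea")
  write_wfdb_header(h, out)
  h2 <- read_wfdb_header(out)
  expect_equal(h2$record_name, h$record_name)
  expect_equal(h2$fs, h$fs)
  expect_equal(h2$n_samples, h$n_samples)
  expect_equal(h2$signals$gain, h$signals$gain)
  expect_equal(h2$signals$lead, h$signals$lead)
})

test_that("a header without a sampling frequency is rejected", {
  path <- withr::local_tempfile(fileext = ".hea")
  writeLines(c("s 1", "s.dat 212 200/mV"), path)
  expect_error(read_wfdb_header(path), "record line")
})

test_that("212 decoding: zero bytes give zero samples", {
  expect_equal(pvcforest:::decode_212(as.raw(c(0, 0, 0)), 2L), c(0L, 0L))
})

test_that("212 encode/decode is the identity on 12-bit two's-complement pairs", {
  # boundary cases across sign and nibble edges
  edge <- c(-2048L, -2047L, -256L, -255L, -1L, 0L, 1L, 255L, 256L, 2047L)
  pairs <- expand.grid(a = edge, b = edge)
  v <- as.integer(rbind(pairs$a, pairs$b))
  expect_identical(pvcforest:::decode_212(pvcforest:::encode_212(v), length(v)), v)

  # random pairs packed by an independently written packer
  set.seed(42)
  w <- sample(-2048:2047, 1000L, replace = TRUE)
  pack_one <- function(s1, s2) {
    u1 <- bitwAnd(s1, 0xFFF); u2 <- bitwAnd(s2, 0xFFF)
    c(bitwAnd(u1, 0xFF),
      bitwOr(bitwShiftR(u1, 8L), bitwShiftL(bitwShiftR(u2, 8L), 4L)),
      bitwAnd(u2, 0xFF))
  }
  bytes <- as.raw(unlist(lapply(seq(1, 1000, by = 2), function(i) {
    pack_one(w[[i]], w[[i + 1L]])
  })))
  expect_identical(pvcforest:::decode_212(bytes, 1000L), w)
})

test_that("truncated 212 files are reported", {
  expect_error(pvcforest:::decode_212(as.raw(c(0, 0, 0)), 4L), "truncated")
})

test_that("text-dialect annotations map directly", {
  path <- withr::local_tempfile()
  writeLines(c("300 N", "660 V"), path)
  ann <- read_annotations(path, dialect = "text")
  expect_equal(ann$sample, c(300L, 660L))
  expect_equal(ann$is_pvc, c(FALSE, TRUE))
  expect_equal(ann$aami, c("N", "V"))
})

test_that("an empty annotation file yields an empty table", {
  path <- withr::local_tempfile()
  writeLines(character(), path)
  ann <- read_annotations(path, dialect = "text")
  expect_equal(nrow(ann), 0L)
})

test_that("binary annotations round-trip, including SKIP escapes", {
  set.seed(7)
  # gaps beyond the 10-bit delta range force SKIP words
  gaps <- sample(c(50:400, 2000:5000), 50L, replace = TRUE)
  ann <- tibble::tibble(
    sample = cumsum(gaps),
    symbol = sample(beat_symbols(), 50L, replace = TRUE)
  )
  path <- withr::local_tempfile(fileext = ".atr")
  write_annotations(ann, path, dialect = "mit")
  back <- read_annotations(path, dialect = "mit")
  expect_identical(back$sample, as.integer(ann$sample))
  expect_identical(back$symbol, ann$symbol)
})

test_that("non-monotone annotation samples are rejected", {
  path <- withr::local_tempfile()
  writeLines(c("660 N", "300 V"), path)
  expect_error(read_annotations(path, dialect = "text"), "increasing")
})

test_that("AAMI mapping follows the EC57 class table", {
  expect_equal(map_symbol_to_aami("V"), "V")
  expect_equal(map_symbol_to_aami("N"), "N")
  expect_equal(map_symbol_to_aami("L"), "N")
  expect_equal(map_symbol_to_aami("E"), "V")
  expect_equal(map_symbol_to_aami("A"), "S")
  expect_equal(map_symbol_to_aami("F"), "F")
  expect_equal(map_symbol_to_aami("f"), "Q")
  expect_error(map_symbol_to_aami("+"), "not a beat annotation")
  # totality: every beat symbol maps, and the binary label is defined
  classes <- map_symbol_to_aami(beat_symbols())
  expect_true(all(classes %in% c("N", "S", "V", "F", "Q")))
  expect_type(to_binary_label(classes), "logical")
})

test_that("only the ventricular class maps to the PVC label", {
  expect_true(to_binary_label("V"))
  expect_false(to_binary_label("F"))
  expect_false(to_binary_label("Q"))
  expect_equal(to_binary_label(c("N", "S", "V", "F", "Q")),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("the DS1/DS2 partition matches the published split", {
  p <- partition_records(c("101", "100", "102"))
  expect_equal(p$dataset, c("DS1", "DS2", "excluded"))
  ds1 <- pvcforest:::.ds1_records
  ds2 <- pvcforest:::.ds2_records
  expect_length(ds1, 22L)
  expect_length(ds2, 22L)
  expect_length(intersect(ds1, ds2), 0L)
  expect_error(partition_records("999"), "not in the")
})

test_that("a written record re-reads within one quantization step", {
  sim <- generate_record(synth_config(n_beats = 20L, pvc_fraction = 0.2, seed = 5))
  dir <- withr::local_tempdir()
  write_wfdb(sim$record, sim$annotations, dir, "s1")
  back <- read_wfdb_record(dir, "s1")
  expect_lte(max(abs(back$record$samples - sim$record$samples)), 1 / 200)
  expect_identical(back$annotations, sim$annotations)
  back_txt <- read_wfdb_record(dir, "s1", ann_dialect = "text")
  expect_identical(back_txt$annotations, sim$annotations)
})

test_that("a missing lead is reported with the available ones", {
  sim <- generate_record(synth_config(n_beats = 5L, seed = 1))
  dir <- withr::local_tempdir()
  write_wfdb(sim$record, sim$annotations, dir, "s1")
  h <- read_wfdb_header(file.path(dir, "s1.hea"))
  expect_error(
    read_wfdb_signal(file.path(dir, "s1.dat"), h, lead = "V5"),
    "available leads: MLII"
  )
})
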