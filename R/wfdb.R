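#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# MIT annotation code <-> symbol table (beat annotations only).
# Codes 1..13, 34, 38 are the standard beat codes; everything else in the
# 6-bit code space is a non-beat annotation and is skipped on read.
.beat_codes <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "e" = 34L, "f" = 38L
)

# AAMI EC57 grouping of MIT beat symbols into the five classes.
.aami_table <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

# Train/test partition of the 44 usable MIT-BIH records; the four
# paced-beat records are always excluded.
.ds1_records <- c(
  "101", "106", "108", "109", "112", "114", "115", "116", "118", "119",
  "122", "124", "201", "203", "205", "207", "208", "209", "215", "220",
  "223", "230"
)
.ds2_records <- c(
  "100", "103", "105", "111", "113", "117", "121", "123", "200", "202",
  "210", "212", "213", "214", "219", "221", "222", "228", "231", "232",
  "233", "234"
)
.excluded_records <- c("102", "104", "107", "217")

#' Beat annotation symbols recognised by the package
#'
#' @return Character vector of single-character MIT beat annotation symbols.
#' @export
beat_symbols <- function() names(.aami_table)

#' Map an MIT beat annotation symbol to its AAMI class
#'
#' The five AAMI classes are N (normal and bundle-branch/escape beats),
#' S (supraventricular ectopic), V (ventricular ectopic, i.e. PVC),
#' F (fusion) and Q (paced/unclassifiable).
#'
#' @param symbol Character vector of single-character beat symbols.
#' @return Character vector of AAMI classes ("N", "S", "V", "F", "Q").
#' @export
#' @examples
#' map_symbol_to_aami(c("V", "N", "L"))
map_symbol_to_aami <- function(symbol) {
  out <- .aami_table[symbol]
  if (anyNA(out)) {
    bad <- unique(symbol[is.na(out)])
    abort(paste0(
      "not a beat annotation symbol: ",
      paste(sprintf("'%s'", bad), collapse = ", ")
    ))
  }
  unname(out)
}

#' Collapse an AAMI class to the binary PVC label
#'
#' The ventricular class V is the positive (PVC) class; N, S, F and Q are
#' all non-PVC.
#'
#' @param aami Character vector of AAMI classes.
#' @return Logical vector, `TRUE` for PVC.
#' @export
to_binary_label <- function(aami) {
  ok <- aami %in% c("N", "S", "V", "F", "Q")
  if (!all(ok)) {
    abort(paste0("unknown AAMI class: ", paste(unique(aami[!ok]), collapse = ", ")))
  }
  aami == "V"
}

#' Partition record names into the DS1/DS2 train-test split
#'
#' The 48 MIT-BIH records are split into 22 training records (DS1) and 22
#' test records (DS2); the four records containing paced beats (102, 104,
#' 107, 217) are always excluded.
#'
#' @param record_names Character vector of record names.
#' @return A tibble with columns `record` and `dataset`
#'   (one of `"DS1"`, `"DS2"`, `"excluded"`).
#' @export
#' @examples
#' partition_records(c("101", "100", "102"))
partition_records <- function(record_names) {
  record_names <- as.character(record_names)
  dataset <- dplyr::case_when(
    record_names %in% .ds1_records ~ "DS1",
    record_names %in% .ds2_records ~ "DS2",
    record_names %in% .excluded_records ~ "excluded",
    TRUE ~ NA_character_
  )
  if (anyNA(dataset)) {
    abort(paste0(
      "record name(s) not in the DS1/DS2/excluded partition: ",
      paste(unique(record_names[is.na(dataset)]), collapse = ", ")
    ))
  }
  tibble(record = record_names, dataset = dataset)
}

# ---------------------------------------------------------------------------
# Header (.hea) reading / writing

#' Read a WFDB header file
#'
#' Parses the record line (record name, signal count, sampling frequency,
#' sample count) and one line per signal (file name, format code, gain,
#' baseline, lead description). Unknown optional fields are ignored.
#'
#' @param path Path to a `.hea` file.
#' @return An object of class `wfdb_header`: a list with `record_name`,
#'   `n_signals`, `fs`, `n_samples` and a `signals` tibble
#'   (`file`, `format`, `gain`, `baseline`, `lead`).
#' @export
read_wfdb_header <- function(path) {
  if (!file.exists(path)) abort(paste0("header file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) abort("empty header file")

  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 3L) {
    abort(paste0("malformed record line (need name, n_signals, fs): ", lines[[1L]]))
  }
  record_name <- rec[[1L]]
  n_signals <- suppressWarnings(as.integer(rec[[2L]]))
  # fs may carry a counter frequency suffix "360/..." -- keep the first part
  fs <- suppressWarnings(as.numeric(strsplit(rec[[3L]], "/")[[1L]][[1L]]))
  n_samples <- if (length(rec) >= 4L) suppressWarnings(as.numeric(rec[[4L]])) else NA_real_
  if (is.na(n_signals) || n_signals < 1L) {
    abort(paste0("malformed signal count in record line: ", lines[[1L]]))
  }
  if (is.na(fs) || fs <= 0) {
    abort(paste0("missing or invalid sampling frequency in record line: ", lines[[1L]]))
  }
  if (length(lines) < 1L + n_signals) {
    abort("header declares more signals than it has signal lines")
  }

  sig <- purrr::map(seq_len(n_signals), function(i) {
    line <- trimws(lines[[1L + i]])
    tok <- strsplit(line, "\\s+")[[1L]]
    if (length(tok) < 2L) abort(paste0("malformed signal line: ", line))
    fmt <- suppressWarnings(as.integer(sub("[x:+].*$", "", tok[[2L]])))
    if (is.na(fmt)) abort(paste0("malformed format code in signal line: ", line))
    gain <- 200
    baseline <- NA_real_
    if (length(tok) >= 3L) {
      gspec <- tok[[3L]]
      m <- regmatches(gspec, regexec("^(-?[0-9.]+)(\\((-?[0-9]+)\\))?(/.*)?$", gspec))[[1L]]
      if (length(m) == 0L) abort(paste0("malformed gain field in signal line: ", line))
      gain <- as.numeric(m[[2L]])
      if (nzchar(m[[4L]])) baseline <- as.numeric(m[[4L]])
    }
    adc_zero <- if (length(tok) >= 5L) suppressWarnings(as.numeric(tok[[5L]])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
    # description = everything after the 8 numeric fields, else last token
    lead <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else tok[[length(tok)]]
    tibble(
      file = tok[[1L]], format = fmt, gain = gain,
      baseline = baseline, lead = lead
    )
  })
  structure(
    list(
      record_name = record_name, n_signals = n_signals, fs = fs,
      n_samples = n_samples, signals = dplyr::bind_rows(sig)
    ),
    class = "wfdb_header"
  )
}

#' Write a WFDB header file
#'
#' @param header A `wfdb_header` object (see [read_wfdb_header()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wfdb_header <- function(header, path) {
  stopifnot(inherits(header, "wfdb_header"))
  rec <- sprintf(
    "%s %d %s %s", header$record_name, header$n_signals,
    format(header$fs, scientific = FALSE),
    format(header$n_samples, scientific = FALSE)
  )
  sig <- purrr::pmap_chr(header$signals, function(file, format, gain, baseline, lead) {
    sprintf(
      "%s %d %s(%d)/mV 12 %d 0 0 0 %s",
      file, format, format(gain, scientific = FALSE), as.integer(baseline),
      as.integer(baseline), lead
    )
  })
  writeLines(c(rec, sig), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Format 212 signal encoding

# Pack 12-bit two's-complement integers (pairs) into raw bytes: byte1 holds
# the low 8 bits of s1, the low nibble of byte2 the high 4 bits of s1, the
# high nibble of byte2 the high 4 bits of s2, byte3 the low 8 bits of s2.
encode_212 <- function(values) {
  stopifnot(all(values >= -2048L & values <= 2047L))
  if (length(values) %% 2L == 1L) values <- c(values, 0L)
  u <- as.integer(values) %% 4096L   # 12-bit two's complement
  s1 <- u[seq(1L, length(u), by = 2L)]
  s2 <- u[seq(2L, length(u), by = 2L)]
  b1 <- s1 %% 256L
  b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
  b3 <- s2 %% 256L
  as.raw(as.vector(rbind(b1, b2, b3)))
}

decode_212 <- function(bytes, n_values) {
  b <- as.integer(bytes)
  if (length(b) %% 3L != 0L) b <- b[seq_len(3L * (length(b) %/% 3L))]
  b1 <- b[seq(1L, length(b), by = 3L)]
  b2 <- b[seq(2L, length(b), by = 3L)]
  b3 <- b[seq(3L, length(b), by = 3L)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  u <- as.vector(rbind(s1, s2))
  if (length(u) < n_values) {
    abort(sprintf(
      "truncated 212 data file: %d values present, %d required",
      length(u), n_values
    ))
  }
  u <- u[seq_len(n_values)]
  ifelse(u >= 2048L, u - 4096L, u)
}

#' Read one lead of a format-212 WFDB signal file
#'
#' Decodes the packed 12-bit samples, de-interleaves the declared signals,
#' and converts the requested lead to physical units:
#' `mV = (raw - baseline) / gain`.
#'
#' @param path Path to the `.dat` file.
#' @param header A `wfdb_header` describing the record.
#' @param lead Lead name to extract (default `"MLII"`). The lead is located
#'   by name wherever it sits; if absent an error lists the available leads.
#' @return An object of class `ecg_record`: list with `samples` (numeric,
#'   mV), `fs`, `lead`, `record_name` and the `header`.
#' @export
read_wfdb_signal <- function(path, header, lead = "MLII") {
  stopifnot(inherits(header, "wfdb_header"))
  idx <- match(lead, header$signals$lead)
  if (is.na(idx)) {
    abort(paste0(
      "lead '", lead, "' not present; available leads: ",
      paste(header$signals$lead, collapse = ", ")
    ))
  }
  if (header$signals$format[[idx]] != 212L) {
    abort(paste0("unsupported signal format ", header$signals$format[[idx]],
                 " (only 212 is supported)"))
  }
  bytes <- readBin(path, what = "raw", n = file.size(path))
  n_total <- header$n_samples * header$n_signals
  raw_vals <- decode_212(bytes, n_total)
  chan <- raw_vals[seq(idx, n_total, by = header$n_signals)]
  samples <- (chan - header$signals$baseline[[idx]]) / header$signals$gain[[idx]]
  new_ecg_record(samples, header$fs, lead = lead,
                 record_name = header$record_name, header = header)
}

new_ecg_record <- function(samples, fs, lead = "MLII", record_name = "synth",
                           header = NULL) {
  stopifnot(is.numeric(samples), fs > 0, all(is.finite(samples)))
  structure(
    list(
      samples = as.numeric(samples), fs = fs, lead = lead,
      record_name = record_name, header = header
    ),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record '%s'> lead %s, %d samples @ %g Hz (%.1f s)\n",
    x$record_name, x$lead, length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Annotations

annotation_tibble <- function(sample, symbol) {
  aami <- map_symbol_to_aami(symbol)
  tibble(
    sample = as.integer(sample), symbol = symbol,
    aami = aami, is_pvc = to_binary_label(aami)
  )
}

#' Read beat annotations
#'
#' Two dialects are supported: the MIT binary annotation format (16-bit
#' words holding a 6-bit type code and a 10-bit time increment, with SKIP
#' escapes for long gaps) and a plain two-column text dialect
#' (`sample symbol` per line). Non-beat annotations are skipped; unknown
#' binary codes are skipped with a warning.
#'
#' @param path Path to the annotation file.
#' @param dialect `"mit"` (binary) or `"text"`.
#' @return A tibble with columns `sample` (1-based), `symbol`, `aami`,
#'   `is_pvc`, sorted by strictly increasing `sample`.
#' @export
read_annotations <- function(path, dialect = c("mit", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "text") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(annotation_tibble(integer(), character()))
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) abort(paste0("malformed annotation line ", bad[[1L]]))
    sample <- as.integer(purrr::map_chr(parts, 1L))
    symbol <- purrr::map_chr(parts, 2L)
    keep <- symbol %in% beat_symbols()
    sample <- sample[keep]; symbol <- symbol[keep]
  } else {
    res <- read_mit_annotations(path)
    sample <- res$sample; symbol <- res$symbol
  }
  if (is.unsorted(sample, strictly = TRUE)) {
    abort("annotation samples are not strictly increasing")
  }
  annotation_tibble(sample, symbol)
}

read_mit_annotations <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.size(path))
  b <- as.integer(bytes)
  code_of <- stats::setNames(names(.beat_codes), .beat_codes)
  sample <- integer(); symbol <- character()
  t_now <- 0; i <- 1L; n <- length(b)
  while (i + 1L <= n) {
    lo <- b[[i]]; hi <- b[[i + 1L]]
    i <- i + 2L
    code <- hi %/% 4L              # top 6 bits of the 16-bit word
    delta <- (hi %% 4L) * 256L + lo  # low 10 bits
    if (code == 0L && delta == 0L) break  # EOF
    if (code == 59L) {             # SKIP: 4-byte interval, high word first
      if (i + 3L > n) abort("truncated SKIP annotation")
      interval <- (b[[i + 1L]] * 256L + b[[i]]) * 65536L +
        (b[[i + 3L]] * 256L + b[[i + 2L]])
      t_now <- t_now + interval
      i <- i + 4L
      next
    }
    if (code == 63L) {             # AUX: delta = byte count, padded to even
      nbytes <- delta + (delta %% 2L)
      i <- i + nbytes
      next
    }
    if (code %in% c(60L, 61L, 62L)) next  # NUM/SUB/CHN: no time advance
    t_now <- t_now + delta
    sym <- unname(code_of[as.character(code)])
    if (is.na(sym)) {
      if (code > 38L) {
        warn(sprintf("skipping unknown annotation code %d", code))
      }
      next  # non-beat annotation
    }
    sample <- c(sample, as.integer(t_now))
    symbol <- c(symbol, sym)
  }
  list(sample = sample, symbol = symbol)
}

#' Write beat annotations
#'
#' Inverse of [read_annotations()]; both the MIT binary dialect and the
#' two-column text dialect round-trip through their readers.
#'
#' @param annotations Tibble with columns `sample` and `symbol`.
#' @param path Output path.
#' @param dialect `"mit"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, dialect = c("mit", "text")) {
  dialect <- match.arg(dialect)
  sample <- as.integer(annotations$sample)
  symbol <- annotations$symbol
  if (dialect == "text") {
    writeLines(sprintf("%d %s", sample, symbol), path)
    return(invisible(path))
  }
  out <- raw()
  t_prev <- 0L
  word <- function(code, delta) {
    v <- code * 1024L + delta
    as.raw(c(v %% 256L, v %/% 256L))
  }
  for (k in seq_along(sample)) {
    delta <- sample[[k]] - t_prev
    if (delta < 0L) abort("annotation samples are not increasing")
    if (delta > 1023L) {
      hi16 <- delta %/% 65536L; lo16 <- delta %% 65536L
      out <- c(out, word(59L, 0L),
               as.raw(c(hi16 %% 256L, hi16 %/% 256L, lo16 %% 256L, lo16 %/% 256L)))
      delta <- 0L
    }
    code <- .beat_codes[[symbol[[k]]]]
    out <- c(out, word(code, delta))
    t_prev <- sample[[k]]
  }
  out <- c(out, as.raw(c(0L, 0L)))  # EOF word
  writeBin(out, path)
  invisible(path)
}
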