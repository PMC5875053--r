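# WFDB (PhysioNet waveform database) I/O: .hea headers, .dat signals in
# formats 212/16/80, and MIT-format annotation files. Hand-written because no
# WFDB reader is available in the installed R stack; only the subset needed
# for MIT-BIH Arrhythmia layout records is covered.

# Standard WFDB annotation code table (code number -> mnemonic).
WFDB_CODE_TABLE <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",        # 1-10
  "j", "/", "Q", "~", "", "|", "", "s", "T", "*",          # 11-20
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",       # 21-30
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")",        # 31-40
  "r")                                                     # 41

#' WFDB beat annotation mnemonics
#'
#' The set of annotation codes that mark an actual heartbeat (QRS complex),
#' as opposed to rhythm changes, signal-quality flags or non-beat events.
#' Matches the QRS subset of the standard WFDB code table; used by
#' [evaluate_record()] to reduce reference annotations to true beats.
#'
#' @return Character vector of beat mnemonics.
#' @export
wfdb_beat_codes <- function() {
  c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
    "j", "/", "Q", "B", "e", "n", "f", "r", "?")
}

parse_gain_spec <- function(tok) {
  # gain token: "200", "200/mV", "200(1024)/mV"
  units <- "mV"
  if (grepl("/", tok, fixed = TRUE)) {
    parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    units <- parts[2]
    tok <- parts[1]
  }
  baseline <- NA_real_
  m <- regmatches(tok, regexec("^([-0-9.eE+]+)\\(([-0-9]+)\\)$", tok))[[1]]
  if (length(m) == 3L) {
    gain <- as.numeric(m[2]); baseline <- as.numeric(m[3])
  } else {
    gain <- suppressWarnings(as.numeric(tok))
  }
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default
  list(gain = gain, baseline = baseline, units = units)
}

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("WFDB header is empty: ", hea_path)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 2L) stop("malformed WFDB record line in ", hea_path)
  record_name <- sub("/.*$", "", rec[1])  # strip segment count if present
  nsig <- as.integer(rec[2])
  fs <- 250  # WFDB default sampling frequency
  if (length(rec) >= 3L) fs <- as.numeric(strsplit(rec[3], "/")[[1]][1])
  nsamp <- if (length(rec) >= 4L) as.integer(rec[4]) else NA_integer_
  if (is.na(nsig) || nsig < 1L) stop("header declares no signals: ", hea_path)
  if (length(lines) < 1L + nsig)
    stop("header declares ", nsig, " signals but has too few lines: ", hea_path)
  sig <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2L) stop("malformed signal line in ", hea_path, ": ", ln)
    fmt <- as.integer(sub("[x:+].*$", "", f[2]))  # drop samples/frame, skew
    g <- if (length(f) >= 3L) parse_gain_spec(f[3]) else parse_gain_spec("200")
    adczero <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(adczero)) adczero <- 0
    baseline <- if (is.na(g$baseline)) adczero else g$baseline
    desc <- if (length(f) >= 9L) paste(f[-(1:8)], collapse = " ") else ""
    list(file = f[1], fmt = fmt, gain = g$gain, baseline = baseline,
         units = g$units, description = desc)
  })
  list(record_name = record_name, nsig = nsig, fs = fs, nsamp = nsamp,
       signals = sig)
}

# Decode a raw byte vector of format-212 data (two 12-bit two's-complement
# samples packed into 3 bytes) into an integer vector.
decode_fmt212 <- function(bytes) {
  nb <- length(bytes)
  ntrip <- nb %/% 3L
  if (ntrip == 0L) return(integer(0))
  b <- as.integer(bytes[seq_len(3L * ntrip)])
  b0 <- b[seq(1L, by = 3L, length.out = ntrip)]
  b1 <- b[seq(2L, by = 3L, length.out = ntrip)]
  b2 <- b[seq(3L, by = 3L, length.out = ntrip)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b1, 0x0FL), 8L), b0)
  s2 <- bitwOr(bitwShiftL(bitwAnd(bitwShiftR(b1, 4L), 0x0FL), 8L), b2)
  fix <- function(s) ifelse(s > 2047L, s - 4096L, s)
  out <- integer(2L * ntrip)
  out[seq(1L, by = 2L, length.out = ntrip)] <- fix(s1)
  out[seq(2L, by = 2L, length.out = ntrip)] <- fix(s2)
  out
}

encode_fmt212 <- function(samples) {
  if (length(samples) %% 2L == 1L) samples <- c(samples, 0L)
  s <- as.integer(samples)
  if (any(s < -2048L | s > 2047L))
    stop("format 212 samples must fit in 12 bits")
  s <- ifelse(s < 0L, s + 4096L, s)
  s1 <- s[seq(1L, length(s), by = 2L)]
  s2 <- s[seq(2L, length(s), by = 2L)]
  b0 <- bitwAnd(s1, 0xFFL)
  b1 <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
  b2 <- bitwAnd(s2, 0xFFL)
  as.raw(rbind(b0, b1, b2))
}

read_dat_signals <- function(dat_path, header) {
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  fmts <- unique(vapply(header$signals, `[[`, numeric(1), "fmt"))
  if (length(fmts) != 1L)
    stop("mixed signal formats in one .dat are not supported")
  fmt <- fmts[1]
  bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  if (!length(bytes)) stop("WFDB signal file is empty: ", dat_path)
  flat <- switch(as.character(fmt),
    "212" = decode_fmt212(bytes),
    "16" = readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little"),
    "80" = as.integer(bytes) - 128L,
    stop("unsupported WFDB signal format: ", fmt))
  nsig <- header$nsig
  nsamp <- length(flat) %/% nsig
  if (!is.na(header$nsamp) && header$nsamp > 0L) nsamp <- min(nsamp, header$nsamp)
  lapply(seq_len(nsig), function(i)
    flat[seq(i, by = nsig, length.out = nsamp)])
}

#' Read a WFDB record (header + signal, optionally annotations)
#'
#' Reads a record in the PhysioNet WFDB layout used by the MIT-BIH
#' Arrhythmia Database: a `.hea` header describing one `.dat` signal file
#' (formats 212, 16 or 80 supported), plus an optional annotation file.
#' ADC counts are converted to physical units via each signal's gain and
#' baseline. Annotation sample numbers are 0-based, as stored.
#'
#' @param path record path with or without the `.hea` extension
#'   (e.g. `"data/100"` or `"data/100.hea"`).
#' @param channel optional channel name or 1-based index; `NULL` keeps all
#'   channels.
#' @param annot annotation file extension to look for (default `"atr"`);
#'   `NULL` skips annotation reading.
#' @return An [ecg_record()]; `annotations` is populated when the annotation
#'   file exists (every stored annotation is kept — filtering to beat codes
#'   is the evaluator's job).
#' @export
read_wfdb_record <- function(path, channel = NULL, annot = "atr") {
  base <- sub("\\.hea$", "", path)
  header <- parse_wfdb_header(paste0(base, ".hea"))
  dat_files <- unique(vapply(header$signals, `[[`, character(1), "file"))
  if (length(dat_files) != 1L)
    stop("records spanning multiple signal files are not supported")
  dat_path <- file.path(dirname(base), dat_files[1])
  adc <- read_dat_signals(dat_path, header)
  phys <- lapply(seq_along(adc), function(i) {
    s <- header$signals[[i]]
    (adc[[i]] - s$baseline) / s$gain
  })
  names <- vapply(seq_along(adc), function(i) {
    d <- header$signals[[i]]$description
    if (nzchar(d)) d else paste0("ch", i)
  }, character(1))
  ann <- NULL
  if (!is.null(annot)) {
    ann_path <- paste0(base, ".", annot)
    if (file.exists(ann_path)) ann <- read_wfdb_annotations(ann_path)
  }
  rec <- ecg_record(phys, fs = header$fs, record_id = header$record_name,
                    channel_names = names, annotations = ann)
  if (!is.null(channel)) {
    i <- resolve_channel(rec, channel)
    rec$channels <- rec$channels[i]
    rec$channel_names <- rec$channel_names[i]
  }
  rec
}

#' Read a WFDB (MIT-format) annotation file
#'
#' Decodes the MIT annotation byte stream: 16-bit little-endian words with a
#' 6-bit type code and 10-bit time increment, honouring SKIP (long
#' intervals), NUM/SUB/CHN modifiers and AUX strings.
#'
#' @param path annotation file (e.g. `"100.atr"`).
#' @return A [beat_annotations()] with 0-based sample indices and mnemonic
#'   codes for every stored annotation.
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  nw <- length(bytes) %/% 2L
  words <- readBin(bytes[seq_len(2L * nw)], "integer", n = nw, size = 2L,
                   signed = FALSE, endian = "little")
  t <- 0
  i <- 1L
  idx <- numeric(0); codes <- character(0)
  while (i <= nw) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    time10 <- bitwAnd(w, 0x3FFL)
    if (code == 0L && time10 == 0L) break  # EOF
    if (code == 59L) {          # SKIP: next 2 words hold a long interval
      if (i + 2L > nw) break
      hi <- words[i + 1L]; lo <- words[i + 2L]
      iv <- hi * 65536 + lo
      if (iv >= 2^31) iv <- iv - 2^32
      t <- t + iv
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN modifiers
      i <- i + 1L
      next
    }
    if (code == 63L) {          # AUX: time10 = byte count, padded to even
      i <- i + 1L + (time10 + time10 %% 2L) %/% 2L
      next
    }
    t <- t + time10
    idx <- c(idx, t)
    codes <- c(codes,
               if (code >= 1L && code <= length(WFDB_CODE_TABLE))
                 WFDB_CODE_TABLE[code] else "Q")
    i <- i + 1L
  }
  # duplicate/out-of-order times can occur across channels; keep first
  ord <- order(idx)
  idx <- idx[ord]; codes <- codes[ord]
  keep <- !duplicated(idx)
  beat_annotations(idx[keep], codes[keep])
}

#' Write a WFDB (MIT-format) annotation file
#'
#' Inverse of [read_wfdb_annotations()] for the simple case: each annotation
#' is stored as a type word with a 10-bit time increment, with SKIP words for
#' intervals of 1024 samples or more.
#'
#' @param annotations a [beat_annotations()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "beat_annotations"))
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  prev <- 0
  for (k in seq_along(annotations$indices)) {
    dt <- annotations$indices[k] - prev
    prev <- annotations$indices[k]
    code <- match(annotations$codes[k], WFDB_CODE_TABLE)
    if (is.na(code)) code <- 13L  # Q: unclassifiable
    if (dt >= 1024) {
      w16(bitwShiftL(59L, 10L))            # SKIP
      w16(dt %/% 65536); w16(dt %% 65536)  # high word, low word
      dt <- 0
    }
    w16(bitwShiftL(code, 10L) + dt)
  }
  w16(0L)  # EOF
  invisible(path)
}

#' Write an ECG record in WFDB format
#'
#' Writes a `.hea` header plus `.dat` signal file (format 16 by default,
#' format 212 supported) and, when the record carries annotations, a
#' companion annotation file. Samples are quantised to ADC counts with the
#' given gain; intended for fixtures and for exporting detector output, not
#' for archival fidelity.
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if missing).
#' @param fmt WFDB signal format: 16 or 212.
#' @param gain ADC counts per mV.
#' @param annot annotation file extension used when annotations are present.
#' @return The record base path (without extension), invisibly.
#' @export
write_wfdb_record <- function(record, dir, fmt = 16, gain = 200,
                              annot = "atr") {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  nsig <- length(record$channels)
  n <- length(record$channels[[1]])
  adc <- lapply(record$channels, function(x) as.integer(round(x * gain)))
  rng <- if (fmt == 212) 2047L else 32767L
  adc <- lapply(adc, function(x) pmax(pmin(x, rng), -rng - 1L))
  flat <- integer(nsig * n)
  for (i in seq_len(nsig)) flat[seq(i, by = nsig, length.out = n)] <- adc[[i]]
  dat_name <- paste0(record$record_id, ".dat")
  con <- file(paste0(base, ".dat"), "wb")
  if (fmt == 212) {
    writeBin(encode_fmt212(flat), con)
  } else if (fmt == 16) {
    writeBin(flat, con, size = 2L, endian = "little")
  } else {
    close(con); stop("unsupported write format: ", fmt)
  }
  close(con)
  hdr <- c(
    sprintf("%s %d %g %d", record$record_id, nsig, record$fs, n),
    vapply(seq_len(nsig), function(i)
      sprintf("%s %d %g(0)/mV 16 0 %d 0 0 %s", dat_name, as.integer(fmt),
              gain, adc[[i]][1], record$channel_names[i]),
      character(1)))
  writeLines(hdr, paste0(base, ".hea"))
  if (!is.null(record$annotations))
    write_wfdb_annotations(record$annotations, paste0(base, ".", annot))
  invisible(base)
}
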