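#' Read an ECG signal from CSV or WFDB files
#'
#' CSV input is one amplitude per line (an optional single header line is
#' skipped); the sampling frequency must be supplied. WFDB input reads the
#' `.hea` header and the binary `.dat` signal file (formats 16 and 212,
#' the formats used by the PhysioNet arrhythmia databases), converting
#' digital units to physical via the per-channel gain and baseline.
#'
#' @param path CSV file path, or WFDB record path (with or without the
#'   `.hea` extension).
#' @param format `"csv"` or `"wfdb"`; default guesses from the extension.
#' @param fs Sampling frequency in Hz; required for CSV, ignored for WFDB
#'   (taken from the header).
#' @param channel Channel to extract, 1-based (default 1, i.e. Lead I in
#'   the standard databases).
#' @return An [ecg_record()].
#' @export
read_signal <- function(path, format = NULL, fs = NULL, channel = 1L) {
  if (is.null(format)) {
    format <- if (grepl("\\.hea$", path) || file.exists(paste0(path, ".hea")))
      "wfdb" else "csv"
  }
  format <- match.arg(format, c("csv", "wfdb"))
  if (format == "csv") {
    if (!file.exists(path)) {
      stop("signal file not found: ", path, call. = FALSE)
    }
    if (is.null(fs)) {
      stop("`fs` must be supplied for CSV input (no header carries it)",
           call. = FALSE)
    }
    lines <- readLines(path)
    first <- suppressWarnings(as.numeric(lines[1]))
    if (length(lines) > 0L && is.na(first)) lines <- lines[-1L]
    x <- suppressWarnings(as.numeric(lines))
    if (any(is.na(x))) {
      stop("CSV signal contains non-numeric lines", call. = FALSE)
    }
    ecg_record(x, fs, record_id = sub("\\.[^.]*$", "", basename(path)))
  } else {
    rec <- read_wfdb_signal(path)
    if (channel < 1L || channel > ncol(rec$signals)) {
      stop(sprintf("bad channel %d; record has channels: %s",
                   channel, paste(seq_len(ncol(rec$signals)),
                                  collapse = ", ")), call. = FALSE)
    }
    ecg_record(rec$signals[, channel], rec$fs, record_id = rec$record_name)
  }
}

#' Write a signal as single-column CSV
#'
#' @param record An [ecg_record()] or numeric vector.
#' @param path Output path.
#' @param header Write a `"amplitude"` header line (default FALSE).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path, header = FALSE) {
  x <- if (is_ecg_record(record)) record$samples else as.numeric(record)
  lines <- format(x, trim = TRUE, digits = 15)
  if (header) lines <- c("amplitude", lines)
  writeLines(lines, path)
  invisible(path)
}

# ---- WFDB (minimal, self-contained) ---------------------------------------

#' Read a WFDB record (header + signal)
#'
#' Minimal reader for the PhysioNet WFDB format family: parses the `.hea`
#' text header and decodes the `.dat` file for formats 16 (16-bit
#' little-endian) and 212 (packed 12-bit pairs). Samples are returned in
#' physical units, `(adc - baseline) / gain` per channel.
#'
#' @param path Record path with or without the `.hea` extension.
#' @return List with `record_name`, `fs`, `n_samples`, `signals` (matrix,
#'   one column per channel, physical units) and `header` (parsed fields).
#' @export
read_wfdb_signal <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  record_name <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[1L + seq_len(nsig)]
  parse_sig <- function(line) {
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    else if (length(f) >= 5) as.numeric(f[5]) else 0   # adc zero fallback
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline)
  }
  info <- lapply(sig, parse_sig)
  fmt <- unique(vapply(info, `[[`, integer(1), "format"))
  if (length(fmt) != 1L || !fmt %in% c(16L, 212L)) {
    stop("only single-format WFDB records in formats 16 or 212 are supported",
         call. = FALSE)
  }
  datfile <- file.path(dirname(hea), info[[1]]$file)
  raw <- readBin(datfile, "raw", n = file.info(datfile)$size)
  adc <- if (fmt == 16L) .decode_fmt16(raw) else .decode_fmt212(raw)
  total <- (length(adc) %/% nsig) * nsig
  adc <- matrix(adc[seq_len(total)], ncol = nsig, byrow = TRUE)
  if (!is.na(nsamp) && nsamp <= nrow(adc)) adc <- adc[seq_len(nsamp), ,
                                                      drop = FALSE]
  phys <- sapply(seq_len(nsig), function(j) {
    (adc[, j] - info[[j]]$baseline) / info[[j]]$gain
  })
  phys <- matrix(phys, ncol = nsig)
  list(record_name = record_name, fs = fs, n_samples = nrow(phys),
       signals = phys, header = info)
}

.decode_fmt16 <- function(raw) {
  n <- length(raw) %/% 2L
  readBin(raw, "integer", n = n, size = 2L, signed = TRUE,
          endian = "little")
}

.decode_fmt212 <- function(raw) {
  n3 <- length(raw) %/% 3L
  b <- as.integer(raw)
  i <- 3L * (seq_len(n3) - 1L)
  s1 <- b[i + 1L] + bitwAnd(b[i + 2L], 15L) * 256L
  s2 <- b[i + 3L] + bitwAnd(b[i + 2L], 240L) / 16L * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

#' Write a WFDB record (header + signal)
#'
#' Counterpart of [read_wfdb_signal()], mainly for round-trip testing and
#' for exporting synthetic fixtures. Physical samples are digitized with
#' the given gain/baseline and clipped to the format's range.
#'
#' @param signals Numeric vector or matrix (one column per channel),
#'   physical units.
#' @param fs Sampling frequency (Hz).
#' @param path Output record path (no extension).
#' @param format 16 or 212.
#' @param gain ADC units per physical unit (default 200).
#' @param baseline ADC value corresponding to physical 0 (default 0).
#' @return `path`, invisibly.
#' @export
write_wfdb_signal <- function(signals, fs, path, format = 16L,
                              gain = 200, baseline = 0) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  nsig <- ncol(signals)
  nsamp <- nrow(signals)
  format <- as.integer(format)
  if (!format %in% c(16L, 212L)) stop("format must be 16 or 212",
                                      call. = FALSE)
  lim <- if (format == 16L) c(-32768L, 32767L) else c(-2048L, 2047L)
  adc <- round(signals * gain + baseline)
  adc <- pmin(pmax(adc, lim[1]), lim[2])
  record_name <- basename(path)
  hea <- c(sprintf("%s %d %g %d", record_name, nsig, fs, nsamp),
           sprintf("%s.dat %d %g(%d)/mV 12 0 0 0 0 ch%d",
                   record_name, format, gain, as.integer(baseline),
                   seq_len(nsig)))
  writeLines(hea, paste0(path, ".hea"))
  flat <- as.integer(t(adc))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con), add = TRUE)
  if (format == 16L) {
    writeBin(flat, con, size = 2L, endian = "little")
  } else {
    if (length(flat) %% 2L == 1L) flat <- c(flat, 0L)
    s1 <- flat[seq(1L, length(flat), by = 2L)]
    s2 <- flat[seq(2L, length(flat), by = 2L)]
    s1 <- ifelse(s1 < 0L, s1 + 4096L, s1)
    s2 <- ifelse(s2 < 0L, s2 + 4096L, s2)
    b1 <- s1 %% 256L
    b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
    b3 <- s2 %% 256L
    writeBin(as.raw(rbind(b1, b2, b3)), con)
  }
  invisible(path)
}

# ---- annotations -----------------------------------------------------------

# WFDB/MIT annotation code table (code -> mnemonic) and beat classes
.wfdb_ann_chars <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
                     "j", "/", "Q", "~", "", "|", "", "s", "T", "*",
                     "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",
                     "!", "[", "]", "e", "n", "@", "x", "f", "(", ")",
                     "r")
.wfdb_beat_codes <- c(1:13, 25, 30, 34, 35, 38, 41)

#' Read beat annotations from a text file or WFDB annotation file
#'
#' Plain text: one 1-based sample index per line (optionally followed by a
#' whitespace-separated label). WFDB: the MIT binary annotation format;
#' only beat-class annotations are kept, and the number of dropped
#' non-beat annotations (rhythm changes, signal-quality marks, etc.) is
#' reported via a message.
#'
#' @param path File path. For WFDB the conventional extension is `.atr`.
#' @param format `"txt"` or `"wfdb"`; default guesses from the extension.
#' @return Object of class `annotation_list`: list with `record_id`,
#'   `sample` (strictly increasing 1-based indices), `label` (character),
#'   `n_excluded` (non-beat annotations dropped).
#' @export
read_annotations <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(atr|qrs|ecg|ann)$", path)) "wfdb" else "txt"
  }
  format <- match.arg(format, c("txt", "wfdb"))
  if (format == "txt") {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t,]+")
    sample <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    if (any(is.na(sample))) stop("non-integer annotation line", call. = FALSE)
    label <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "N", "")
    n_excl <- 0L
  } else {
    ann <- .read_mit_annotations(path)
    beat <- ann$code %in% .wfdb_beat_codes
    n_excl <- sum(!beat)
    if (n_excl > 0L) {
      message(sprintf("read_annotations: dropped %d non-beat annotation(s)",
                      n_excl))
    }
    sample <- ann$sample[beat]
    label <- vapply(ann$code[beat], function(cd) {
      if (cd >= 1L && cd <= length(.wfdb_ann_chars)) .wfdb_ann_chars[cd]
      else "?"
    }, "")
  }
  if (length(sample) > 1L && is.unsorted(sample, strictly = TRUE)) {
    stop("annotation indices must be strictly increasing", call. = FALSE)
  }
  if (any(sample < 1L)) stop("annotation index out of range", call. = FALSE)
  structure(list(record_id = sub("\\.[^.]*$", "", basename(path)),
                 sample = sample, label = label, n_excluded = n_excl),
            class = "annotation_list")
}

#' @export
print.annotation_list <- function(x, ...) {
  cat(sprintf("<annotation_list> '%s': %d beats (%d non-beat excluded)\n",
              x$record_id, length(x$sample), x$n_excluded))
  invisible(x)
}

#' Write beat annotations
#'
#' Text output is newline-delimited 1-based sample indices (diffable and
#' trivially parseable); `format = "wfdb"` writes the MIT binary
#' annotation format.
#'
#' @param sample Strictly increasing integer sample indices (1-based).
#' @param path Output path.
#' @param format `"txt"` or `"wfdb"`.
#' @param code Integer WFDB annotation codes (recycled; default 1,
#'   "normal beat"), used only for WFDB output.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(sample, path, format = c("txt", "wfdb"),
                              code = 1L) {
  format <- match.arg(format)
  if (format == "txt") {
    writeLines(as.character(as.integer(sample)), path)
  } else {
    .write_mit_annotations(path, as.integer(sample),
                           rep_len(as.integer(code), length(sample)))
  }
  invisible(path)
}

# MIT annotation binary format: 2-byte little-endian words, top 6 bits
# the annotation code, low 10 bits the sample interval since the previous
# annotation. Code 59 (SKIP) carries a 4-byte interval in the next two
# words (high word first); codes 60-63 carry side information; a zero
# word terminates the stream. Times are stored 0-based; converted to
# this package's 1-based convention on read/write.
.read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  nw <- length(b) %/% 2L
  sample <- integer(0); code <- integer(0)
  t <- 0L; i <- 1L
  while (i <= nw) {
    w <- b[2L * i - 1L] + 256L * b[2L * i]
    cd <- w %/% 1024L
    iv <- w %% 1024L
    i <- i + 1L
    if (cd == 0L && iv == 0L) break
    if (cd == 59L) {                       # SKIP: long interval follows
      if (i + 1L > nw) break
      hi <- b[2L * i - 1L] + 256L * b[2L * i]
      lo <- b[2L * (i + 1L) - 1L] + 256L * b[2L * (i + 1L)]
      t <- t + hi * 65536L + lo
      i <- i + 2L
    } else if (cd >= 60L && cd <= 62L) {   # NUM/SUB/CHN: ignore payload
      next
    } else if (cd == 63L) {                # AUX: skip padded byte count
      i <- i + (iv + iv %% 2L) %/% 2L
    } else {
      t <- t + iv
      sample <- c(sample, t + 1L)          # 0-based file -> 1-based API
      code <- c(code, cd)
    }
  }
  list(sample = sample, code = code)
}

.write_mit_annotations <- function(path, sample, code) {
  stopifnot(length(sample) == length(code))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  t <- 0L
  for (k in seq_along(sample)) {
    iv <- (sample[k] - 1L) - t
    if (iv < 0L) stop("annotation samples must be increasing", call. = FALSE)
    if (iv > 1023L) {
      hi <- iv %/% 65536L
      lo <- iv %% 65536L
      writeBin(as.raw(c(0L, 236L)), con)               # SKIP word (59 << 10)
      writeBin(as.raw(c(hi %% 256L, hi %/% 256L)), con)
      writeBin(as.raw(c(lo %% 256L, lo %/% 256L)), con)
      iv <- 0L
    }
    w <- code[k] * 1024L + iv
    writeBin(as.raw(c(w %% 256L, w %/% 256L)), con)
    t <- sample[k] - 1L
  }
  writeBin(as.raw(c(0L, 0L)), con)
  invisible(path)
}
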