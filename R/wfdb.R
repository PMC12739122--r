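## Minimal native WFDB reader: header (.hea), signal formats 212 and 16,
## and MIT-format beat annotations (.atr). Only the subset of the format
## family needed for standard two-lead arrhythmia records is supported.

## annotation code -> display symbol (standard WFDB code table)
WFDB_CODE_SYMBOLS <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",   # 1-10
  "j", "/", "Q", "~", "", "|", "", "s", "T", "*",     # 11-20
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",  # 21-30
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")",   # 31-40
  "r")                                                # 41

#' Read a WFDB record header
#'
#' Parses the record line (name, number of signals, sampling frequency,
#' number of samples) and per-signal lines (file name, storage format, ADC
#' gain, baseline, description). Formats 212 and 16 are supported by
#' [read_wfdb_record()].
#'
#' @param path path to the `.hea` file.
#' @return list with `record`, `n_sig`, `fs`, `n_samples` and a data frame
#'   `signals`.
#' @export
read_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 3) stop_invalid("malformed WFDB header record line")
  n_sig <- as.integer(rec[2L])
  fs <- as.numeric(sub("/.*$", "", rec[3L]))
  n_samples <- if (length(rec) >= 4) as.integer(rec[4L]) else NA_integer_
  sig_lines <- lines[seq_len(n_sig) + 1L]
  sig <- lapply(sig_lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", f[2L]))
    gain_field <- f[3L]
    units <- if (grepl("/", gain_field)) sub("^.*/", "", gain_field) else "adu"
    gain_field <- sub("/.*$", "", gain_field)
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)) else NA_real_
    gain <- as.numeric(sub("\\(.*$", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    adc_zero <- if (length(f) >= 5) as.numeric(f[5L]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    data.frame(file = f[1L], format = fmt, gain = gain, baseline = baseline,
               units = units, adc_zero = adc_zero, description = desc,
               stringsAsFactors = FALSE)
  })
  list(record = rec[1L], n_sig = n_sig, fs = fs, n_samples = n_samples,
       signals = do.call(rbind, sig))
}

## unpack format 212: 3 bytes hold two 12-bit two's-complement samples
unpack_212 <- function(bytes, n_values) {
  n_triplets <- length(bytes) %/% 3L
  b <- matrix(as.integer(bytes[seq_len(3L * n_triplets)]), nrow = 3L)
  s1 <- bitwOr(bitwShiftL(bitwAnd(b[2L, ], 0x0FL), 8L), b[1L, ])
  s2 <- bitwOr(bitwShiftL(bitwAnd(b[2L, ], 0xF0L), 4L), b[3L, ])
  vals <- as.vector(rbind(s1, s2))
  vals <- ifelse(vals >= 2048L, vals - 4096L, vals)
  vals[seq_len(min(n_values, length(vals)))]
}

#' Read a WFDB record (signal formats 212 and 16)
#'
#' Reads `<prefix>.hea` and the signal file(s) it names, converts ADC units
#' to physical units via `(adc - baseline) / gain`, and returns the signals
#' as a samples x leads matrix.
#'
#' @param prefix record path without extension (e.g. `"mitdb/100"`).
#' @return list with `signal` (matrix), `fs`, `record`, `lead_names`.
#' @export
read_wfdb_record <- function(prefix) {
  hdr <- read_wfdb_header(paste0(prefix, ".hea"))
  dat_file <- file.path(dirname(prefix), hdr$signals$file[1L])
  if (length(unique(hdr$signals$file)) != 1L)
    stop_invalid("multi-file records are not supported")
  fmt <- hdr$signals$format[1L]
  n_sig <- hdr$n_sig
  raw_bytes <- readBin(dat_file, "raw", n = file.size(dat_file))
  if (fmt == 212L) {
    n_vals <- if (is.na(hdr$n_samples)) (length(raw_bytes) %/% 3L) * 2L
              else hdr$n_samples * n_sig
    vals <- unpack_212(raw_bytes, n_vals)
  } else if (fmt == 16L) {
    vals <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                    size = 2L, signed = TRUE, endian = "little")
    if (!is.na(hdr$n_samples)) vals <- vals[seq_len(hdr$n_samples * n_sig)]
  } else stop_invalid("unsupported WFDB signal format: ", fmt)
  n_samp <- length(vals) %/% n_sig
  adc <- matrix(vals[seq_len(n_samp * n_sig)], ncol = n_sig, byrow = TRUE)
  phys <- sweep(sweep(adc, 2L, hdr$signals$baseline, "-"),
                2L, hdr$signals$gain, "/")
  list(signal = phys, fs = hdr$fs, record = hdr$record,
       lead_names = hdr$signals$description)
}

#' Read a MIT-format WFDB annotation file
#'
#' Decodes the 16-bit annotation word stream: beat/non-beat codes with
#' cumulative sample times, honouring the SKIP (long interval), NUM, SUB,
#' CHN and AUX pseudo-annotations.
#'
#' @param path path to the annotation file (e.g. `"100.atr"`).
#' @return data frame with columns `sample` (1-based sample index) and
#'   `symbol` (annotation display symbol).
#' @export
read_wfdb_annotation <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  words <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  times <- integer(0); symbols <- character(0)
  t_cur <- 0; i <- 1L
  while (i <= length(words)) {
    w <- words[i]; i <- i + 1L
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (code == 0L && delta == 0L) break                 # EOF
    if (code == 59L) {                                   # SKIP: 4-byte interval
      if (delta == 0L) {
        hi <- words[i]; lo <- words[i + 1L]; i <- i + 2L
        t_cur <- t_cur + hi * 65536 + lo
      } else t_cur <- t_cur + delta
      next
    }
    if (code == 63L) {                                   # AUX: delta = byte count
      i <- i + (delta + delta %% 2L) %/% 2L
      next
    }
    if (code %in% c(60L, 61L, 62L)) next                 # NUM / SUB / CHN
    t_cur <- t_cur + delta
    sym <- if (code >= 1L && code <= length(WFDB_CODE_SYMBOLS))
      WFDB_CODE_SYMBOLS[code] else ""
    times <- c(times, t_cur)
    symbols <- c(symbols, sym)
  }
  data.frame(sample = times + 1L, symbol = symbols, stringsAsFactors = FALSE)
}

#' Load and preprocess a WFDB record into a beat dataset
#'
#' Convenience pipeline: read the record and its annotations, band-pass
#' filter the chosen lead, and segment annotated beats into fixed windows
#' with the AAMI five-class mapping ([segment_beats()]).
#'
#' @param prefix record path without extension.
#' @param annotator annotation file extension (default `"atr"`).
#' @param lead lead (column) index to use; default 1 (MLII in most records).
#' @param window_len beat window in samples.
#' @param low,high band-pass edges in Hz.
#' @return as [segment_beats()].
#' @export
load_wfdb_beats <- function(prefix, annotator = "atr", lead = 1L,
                            window_len = 360L, low = 0.5, high = 50) {
  rec <- read_wfdb_record(prefix)
  ann <- read_wfdb_annotation(paste0(prefix, ".", annotator))
  x <- bandpass_filter(rec$signal[, lead], fs = rec$fs, low = low, high = high)
  segment_beats(x, ann$sample, ann$symbol, window_len = window_len,
                source_record = rec$record)
}
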