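## Preprocessing, annotation mapping, beat segmentation, splitting and
## augmentation for single-lead ECG.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the output has zero phase shift and the same
#' length as the input. The default band 0.5-50 Hz removes baseline drift
#' and power-line interference while preserving P-QRS-T morphology.
#'
#' @param x numeric signal vector.
#' @param fs sampling frequency in Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @return filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.5, high = 50) {
  assert_scalar_number(fs, "fs"); assert_scalar_number(low, "low")
  assert_scalar_number(high, "high")
  if (!(low > 0 && low < high && high < fs / 2))
    stop_invalid("band edges must satisfy 0 < low < high < fs/2")
  if (length(x) <= 3 * 8)  # forward-backward 4th-order band-pass: 8 states
    stop_invalid("signal too short for the filter order")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  ## odd-reflection padding long enough for the low-frequency corner's
  ## transient, so the zero-phase pass does not ring at the record edges
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Z-score normalization
#'
#' Centers to zero mean and scales to unit sample standard deviation.
#' Constant signals have no scale and raise a degenerate-input error.
#'
#' @param x numeric vector of length >= 2.
#' @return normalized vector.
#' @export
zscore_normalize <- function(x) {
  if (length(x) < 2) stop_invalid("signal must have length >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop_degenerate("constant signal has no z-score (sd = 0)")
  (x - mean(x)) / s
}

## Beat-annotation symbol -> AAMI class. The five-class grouping of the
## standard arrhythmia-archive beat symbols.
AAMI_SYMBOL_MAP <- c(
  N = "N", L = "N", R = "N", e = "N", j = "N",
  A = "S", a = "S", J = "S", S = "S",
  V = "V", E = "V",
  F = "F",
  f = "Q", u = "Q")

#' Map a beat annotation symbol to its AAMI five-class label
#'
#' Symbols map as: `N,L,R,e,j -> N` (normal / bundle-branch block / escape),
#' `A,a,J,S -> S` (supraventricular ectopic), `V,E -> V` (ventricular
#' ectopic), `F -> F` (fusion), `f,u -> Q` (unclassifiable/artifact).
#'
#' @param symbol single-character annotation symbol.
#' @return one of `"N","S","V","F","Q"`.
#' @export
map_annotation_symbol <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L)
    stop_invalid("symbol must be a single character")
  out <- AAMI_SYMBOL_MAP[symbol]
  if (is.na(out))
    stop(structure(class = c("beatformer_unmapped_symbol", "error", "condition"),
                   list(message = paste0("unmapped annotation symbol: '", symbol, "'"),
                        call = sys.call())))
  unname(out)
}

is_mappable_symbol <- function(symbol) symbol %in% names(AAMI_SYMBOL_MAP)

#' Segment annotated heartbeats out of a continuous record
#'
#' For each annotated R peak at (1-based) sample `r` with a mappable beat
#' symbol, extracts the window covering samples
#' `[r - floor(w/2), r + ceil(w/2) - 1]` (length `w`, centered on the R
#' peak). Beats whose window crosses a record boundary, and annotations whose
#' symbol has no AAMI class, are skipped and counted.
#'
#' @param x numeric signal vector (one lead, already filtered).
#' @param r_peaks strictly increasing 1-based sample indices of annotated
#'   beats.
#' @param symbols annotation symbols, same length as `r_peaks`.
#' @param window_len beat window length in samples.
#' @param source_record record name stored in the output metadata.
#' @param normalize if `TRUE` (default), z-score each extracted beat.
#' @return list with `dataset` (a [beat_dataset()]), and counts
#'   `n_segments`, `n_skipped_boundary`, `n_skipped_unmapped`; the three
#'   always sum to `length(r_peaks)`.
#' @export
segment_beats <- function(x, r_peaks, symbols, window_len = 360L,
                          source_record = NA_character_, normalize = TRUE) {
  if (length(r_peaks) != length(symbols))
    stop_invalid("r_peaks and symbols must have the same length")
  if (length(r_peaks) > 1 && any(diff(r_peaks) <= 0))
    stop_invalid("r_peaks must be strictly increasing")
  window_len <- as.integer(window_len)
  if (window_len > length(x))
    stop_invalid("window_len exceeds the record length")
  half_lo <- window_len %/% 2L
  half_hi <- window_len - half_lo  # ceil(w/2)
  segs <- list(); labs <- character(); peaks <- integer()
  n_boundary <- 0L; n_unmapped <- 0L
  for (i in seq_along(r_peaks)) {
    if (!is_mappable_symbol(symbols[i])) { n_unmapped <- n_unmapped + 1L; next }
    r <- as.integer(r_peaks[i])
    lo <- r - half_lo; hi <- r + half_hi - 1L
    if (lo < 1L || hi > length(x)) { n_boundary <- n_boundary + 1L; next }
    seg <- x[lo:hi]
    if (normalize) seg <- zscore_normalize(seg)
    segs[[length(segs) + 1L]] <- seg
    labs <- c(labs, map_annotation_symbol(symbols[i]))
    peaks <- c(peaks, r)
  }
  X <- if (length(segs)) do.call(rbind, segs) else matrix(numeric(), 0L, window_len)
  ds <- beat_dataset(X, labs, vocab = c("N", "S", "V", "F", "Q"),
                     meta = data.frame(
                       source_record = rep(source_record, length(labs)),
                       r_peak = peaks))
  list(dataset = ds, n_segments = length(labs),
       n_skipped_boundary = n_boundary, n_skipped_unmapped = n_unmapped)
}

## per-class counts via largest-remainder rounding, so each split count
## differs from count*fraction by < 1 and the three sum to the class total
split_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test split tags
#'
#' Tags every beat with one of `train`, `val`, `test`. With
#' `stratified = TRUE` (default) the split is drawn independently within each
#' class, with per-class counts rounded by largest remainder so each count
#' differs from `class_count * fraction` by less than 1. A class with fewer
#' beats than splits cannot be stratified and is kept whole in `train`, with
#' a warning.
#'
#' @param dataset a [beat_dataset()].
#' @param fractions length-3 positive numeric `(train, val, test)` summing
#'   to 1.
#' @param rng_seed integer seed; the assignment is deterministic given seed.
#' @param stratified draw the split within each class (default `TRUE`).
#' @return the dataset with its `split` field assigned.
#' @export
split_dataset <- function(dataset, fractions = c(0.7, 0.1, 0.2),
                          rng_seed = 1L, stratified = TRUE) {
  stopifnot(inherits(dataset, "beat_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_invalid("fractions must be three positive numbers summing to 1")
  set.seed(as.integer(rng_seed))
  n <- length(dataset$labels)
  tags <- rep(NA_character_, n)
  tag_levels <- c("train", "val", "test")
  groups <- if (stratified) split(seq_len(n), dataset$labels) else list(all = seq_len(n))
  for (idx in groups) {
    m <- length(idx)
    if (m == 0L) next
    if (stratified && m < 3L) {
      warning("class with fewer beats than splits kept whole in train")
      tags[idx] <- "train"
      next
    }
    counts <- split_counts(m, fractions)
    assignment <- sample(rep(tag_levels, times = counts))
    tags[idx] <- assignment
  }
  dataset$split <- tags
  dataset
}

#' Extract the beats of one split
#'
#' @param dataset a [beat_dataset()] with split tags assigned.
#' @param which one of `"train"`, `"val"`, `"test"`, `"unassigned"`.
#' @return a `beat_dataset` restricted to that split.
#' @export
dataset_split <- function(dataset, which) {
  keep <- dataset$split == which
  beat_dataset(dataset$X[keep, , drop = FALSE], dataset$labels[keep],
               vocab = dataset$vocab, split = dataset$split[keep],
               meta = dataset$meta[keep, , drop = FALSE])
}

#' Time-stretch and amplitude-scale a beat
#'
#' The beat is linearly resampled to `round(stretch_factor * w)` samples
#' (stretching its waves in time), then center-cropped or zero-padded back to
#' the original length `w`, and finally multiplied by `scale_factor`.
#'
#' @param samples numeric beat vector.
#' @param stretch_factor time-stretch in `[0.5, 2]`.
#' @param scale_factor positive amplitude multiplier.
#' @return augmented beat, same length as the input.
#' @export
augment_beat <- function(samples, stretch_factor = 1, scale_factor = 1) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop_invalid("samples must be a numeric vector of length >= 2")
  if (stretch_factor < 0.5 || stretch_factor > 2)
    stop_invalid("stretch_factor must lie in [0.5, 2]")
  if (scale_factor <= 0) stop_invalid("scale_factor must be > 0")
  w <- length(samples)
  new_len <- max(2L, as.integer(round(stretch_factor * w)))
  y <- if (new_len == w) samples else
    stats::approx(x = seq(0, 1, length.out = w), y = samples,
                  xout = seq(0, 1, length.out = new_len))$y
  if (new_len > w) {          # center crop
    start <- (new_len - w) %/% 2L + 1L
    y <- y[start:(start + w - 1L)]
  } else if (new_len < w) {   # center zero-pad
    pad_lo <- (w - new_len) %/% 2L
    y <- c(numeric(pad_lo), y, numeric(w - new_len - pad_lo))
  }
  y * scale_factor
}

#' Augment the minority classes of the training split
#'
#' Appends one augmented copy (random stretch and scale, drawn uniformly
#' from the given ranges) of each training beat whose class is in `classes`.
#' Only the training split is touched; augmented copies are tagged `train`.
#'
#' @param dataset a split [beat_dataset()].
#' @param classes labels to augment (default the minority classes
#'   `S, V, F, Q`).
#' @param stretch_range,scale_range uniform draw ranges (defaults
#'   `[0.9, 1.1]` and `[0.8, 1.2]`).
#' @param rng_seed integer seed.
#' @return the dataset with augmented training beats appended.
#' @export
augment_dataset <- function(dataset, classes = c("S", "V", "F", "Q"),
                            stretch_range = c(0.9, 1.1),
                            scale_range = c(0.8, 1.2), rng_seed = 1L) {
  stopifnot(inherits(dataset, "beat_dataset"))
  set.seed(as.integer(rng_seed))
  idx <- which(dataset$split == "train" & dataset$labels %in% classes)
  if (!length(idx)) return(dataset)
  aug <- matrix(0, nrow = length(idx), ncol = ncol(dataset$X))
  for (k in seq_along(idx)) {
    aug[k, ] <- augment_beat(dataset$X[idx[k], ],
                             stats::runif(1, stretch_range[1], stretch_range[2]),
                             stats::runif(1, scale_range[1], scale_range[2]))
  }
  beat_dataset(rbind(dataset$X, aug),
               c(dataset$labels, dataset$labels[idx]),
               vocab = dataset$vocab,
               split = c(dataset$split, rep("train", length(idx))),
               meta = rbind(dataset$meta, dataset$meta[idx, , drop = FALSE]))
}

#' Write a split manifest as plain text
#'
#' One line per beat: `index<TAB>split_tag`.
#' @param dataset a split [beat_dataset()].
#' @param path output file.
#' @export
write_split_manifest <- function(dataset, path) {
  writeLines(paste(seq_along(dataset$split), dataset$split, sep = "\t"), path)
  invisible(path)
}
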