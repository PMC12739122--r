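## Synthetic heartbeat generator.
##
## Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) on the unit
## interval, sampled at `window_len` points, plus i.i.d. Gaussian noise and a
## per-beat timing jitter shared by all waves. Class identity is carried by
## the wave parameters: morphology differences between templates are what a
## downstream classifier has to learn.

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

#' Define a heartbeat template
#'
#' A template fixes the morphology of one beat class as five Gaussian bumps
#' (P, Q, R, S, T), each described by a center (fraction of the beat window
#' in `[0,1]`), a width (fraction of the window, the Gaussian sigma) and an
#' amplitude (dimensionless, mV-like). Noise and timing jitter are drawn per
#' beat at generation time.
#'
#' @param class_label single class label, one of `"N","S","V","F","Q"` (or any
#'   label used consistently by the caller).
#' @param waves data frame with rownames `P,Q,R,S,T` and columns
#'   `center`, `width`, `amplitude`. Widths must be positive; centers of waves
#'   with nonzero amplitude must be strictly increasing in P<Q<R<S<T order.
#' @param noise_sd standard deviation of additive white noise (>= 0).
#' @param jitter_sd standard deviation of the per-beat shift applied to all
#'   wave centers, as a fraction of the window (>= 0).
#' @param random_amplitude if `TRUE`, wave amplitudes are redrawn uniformly
#'   per beat from `amplitude_range`, producing low-structure beats (used for
#'   the unclassifiable/artifact class).
#' @param amplitude_range length-2 numeric range for `random_amplitude` draws.
#' @return an object of class `beat_template`.
#' @seealso [default_beat_templates()], [generate_beat()]
#' @export
beat_template <- function(class_label, waves, noise_sd = 0, jitter_sd = 0,
                          random_amplitude = FALSE,
                          amplitude_range = c(-0.5, 0.5)) {
  if (!is.character(class_label) || length(class_label) != 1L || !nzchar(class_label))
    stop_invalid("class_label must be a single non-empty string")
  if (!is.data.frame(waves) || !all(WAVE_NAMES %in% rownames(waves)) ||
      !all(c("center", "width", "amplitude") %in% colnames(waves)))
    stop_invalid("waves must be a data frame with rows P,Q,R,S,T and columns center,width,amplitude")
  waves <- waves[WAVE_NAMES, c("center", "width", "amplitude")]
  if (any(!is.finite(as.matrix(waves))))
    stop_invalid("wave parameters must all be finite")
  if (any(waves$width <= 0)) stop_invalid("wave widths must be > 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  present <- waves$amplitude != 0
  if (sum(present) > 1L && any(diff(waves$center[present]) <= 0))
    stop_invalid("centers of present waves must be strictly increasing P<Q<R<S<T")
  structure(list(class_label = class_label, waves = waves,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 random_amplitude = isTRUE(random_amplitude),
                 amplitude_range = amplitude_range),
            class = "beat_template")
}

#' Default class templates for the five AAMI heartbeat classes
#'
#' Morphologies are chosen so that classes differ the way their clinical
#' counterparts do, at cartoon level: `N` is a canonical P-QRS-T beat centered
#' on the R peak; `S` (supraventricular ectopic) has its P wave shifted
#' earlier by 0.08 of the window; `V` (ventricular ectopic) has a 3x widened
#' R wave and no P wave; `F` (fusion) averages the N and V wave parameters;
#' `Q` (unclassifiable/artifact) redraws all amplitudes uniformly per beat, so
#' it has no stable morphology.
#'
#' @param noise_sd,jitter_sd noise and timing-jitter levels shared by all
#'   templates (defaults 0.03 and 0.01).
#' @return named list of [beat_template()] objects for N, S, V, F, Q.
#' @export
default_beat_templates <- function(noise_sd = 0.03, jitter_sd = 0.01) {
  n_waves <- data.frame(
    center    = c(0.30, 0.45, 0.50, 0.55, 0.72),
    width     = c(0.030, 0.015, 0.020, 0.015, 0.050),
    amplitude = c(0.25, -0.12, 1.00, -0.25, 0.35),
    row.names = WAVE_NAMES)
  s_waves <- n_waves
  s_waves["P", "center"] <- n_waves["P", "center"] - 0.08
  v_waves <- n_waves
  v_waves["R", "width"] <- n_waves["R", "width"] * 3
  v_waves["P", "amplitude"] <- 0
  f_waves <- (n_waves + v_waves) / 2
  list(
    N = beat_template("N", n_waves, noise_sd, jitter_sd),
    S = beat_template("S", s_waves, noise_sd, jitter_sd),
    V = beat_template("V", v_waves, noise_sd, jitter_sd),
    F = beat_template("F", f_waves, noise_sd, jitter_sd),
    Q = beat_template("Q", n_waves, noise_sd, jitter_sd,
                      random_amplitude = TRUE))
}

## Core sampler, assumes the RNG state is already set by the caller.
generate_beat_impl <- function(template, window_len) {
  t_grid <- (seq_len(window_len) - 1L) / window_len
  waves <- template$waves
  shift <- if (template$jitter_sd > 0) stats::rnorm(1L, 0, template$jitter_sd) else 0
  amps <- waves$amplitude
  if (template$random_amplitude) {
    amps <- stats::runif(nrow(waves), template$amplitude_range[1L],
                         template$amplitude_range[2L])
  }
  y <- numeric(window_len)
  for (w in seq_len(nrow(waves))) {
    if (amps[w] == 0) next
    mu <- waves$center[w] + shift
    y <- y + amps[w] * exp(-(t_grid - mu)^2 / (2 * waves$width[w]^2))
  }
  if (template$noise_sd > 0)
    y <- y + stats::rnorm(window_len, 0, template$noise_sd)
  y
}

#' Generate a single synthetic heartbeat
#'
#' Evaluates the template's five Gaussian bumps on `window_len` equally
#' spaced points of `[0,1]`, applies one per-beat timing jitter shared by all
#' waves, and adds white Gaussian noise. The same `rng_seed` always yields
#' the identical vector.
#'
#' @param template a [beat_template()].
#' @param window_len number of samples per beat (>= 32; default 360, one
#'   second at 360 Hz).
#' @param rng_seed integer seed.
#' @return numeric vector of length `window_len` with attributes `label`.
#' @examples
#' tpl <- default_beat_templates(noise_sd = 0)$N
#' beat <- generate_beat(tpl, window_len = 360, rng_seed = 1)
#' @export
generate_beat <- function(template, window_len = 360L, rng_seed = 1L) {
  if (!inherits(template, "beat_template")) stop_invalid("template must be a beat_template")
  assert_scalar_number(window_len, "window_len")
  if (window_len < 32) stop_invalid("window_len must be >= 32")
  set.seed(as.integer(rng_seed))
  y <- generate_beat_impl(template, as.integer(window_len))
  attr(y, "label") <- template$class_label
  y
}

#' Generate a labeled synthetic beat dataset
#'
#' @param class_counts named integer vector, beats per class label.
#' @param templates named list of [beat_template()]s covering every label in
#'   `class_counts`; default [default_beat_templates()].
#' @param window_len samples per beat.
#' @param rng_seed integer seed; identical inputs and seed give bit-identical
#'   datasets.
#' @return a `beat_dataset`: list with `X` (beats x samples matrix), `labels`
#'   (character), `vocab` (ordered class vocabulary), `split` (per-beat tag,
#'   initially `"unassigned"`) and `meta` (per-beat source data frame).
#' @examples
#' ds <- generate_dataset(c(N = 10, V = 5), rng_seed = 7)
#' table(ds$labels)
#' @export
generate_dataset <- function(class_counts, templates = default_beat_templates(),
                             window_len = 360L, rng_seed = 1L) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
    stop_invalid("class_counts must be a named vector")
  if (any(class_counts < 0)) stop_invalid("class counts must be >= 0")
  missing_tpl <- setdiff(names(class_counts), names(templates))
  if (length(missing_tpl))
    stop_config("no template for requested label(s): ",
                paste(missing_tpl, collapse = ", "))
  window_len <- as.integer(window_len)
  if (window_len < 32) stop_invalid("window_len must be >= 32")
  set.seed(as.integer(rng_seed))
  total <- sum(class_counts)
  X <- matrix(0, nrow = total, ncol = window_len)
  labels <- character(total)
  i <- 0L
  for (lab in names(class_counts)) {
    for (k in seq_len(class_counts[[lab]])) {
      i <- i + 1L
      X[i, ] <- generate_beat_impl(templates[[lab]], window_len)
      labels[i] <- lab
    }
  }
  beat_dataset(X, labels, vocab = names(class_counts),
               meta = data.frame(source_record = rep("synthetic", total),
                                 r_peak = rep(NA_integer_, total)))
}

#' Construct a beat dataset container
#'
#' @param X numeric matrix, one beat per row.
#' @param labels character vector, one label per row of `X`.
#' @param vocab ordered class vocabulary; defaults to the sorted unique labels.
#' @param split per-beat split tag in
#'   `c("train","val","test","unassigned")`; default all `"unassigned"`.
#' @param meta optional per-beat data frame (source record, R-peak index).
#' @return object of class `beat_dataset`.
#' @export
beat_dataset <- function(X, labels, vocab = NULL, split = NULL, meta = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (nrow(X) != length(labels))
    stop_invalid("labels must have one entry per row of X")
  vocab <- vocab %||% sort(unique(labels))
  if (length(labels) && !all(labels %in% vocab))
    stop_invalid("every label must appear in the vocabulary")
  split <- split %||% rep("unassigned", nrow(X))
  if (!all(split %in% c("train", "val", "test", "unassigned")))
    stop_invalid("split tags must be train/val/test/unassigned")
  if (length(split) != nrow(X)) stop_invalid("one split tag per beat required")
  meta <- meta %||% data.frame(source_record = rep(NA_character_, nrow(X)),
                               r_peak = rep(NA_integer_, nrow(X)))
  structure(list(X = X, labels = labels, vocab = vocab, split = split,
                 meta = meta), class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples, classes: %s\n",
              nrow(x$X), ncol(x$X), paste(x$vocab, collapse = ",")))
  tab <- table(factor(x$labels, levels = x$vocab))
  cat("  counts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (any(x$split != "unassigned")) {
    st <- table(x$split)
    cat("  split: ", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  }
  invisible(x)
}

#' Class counts mirroring the imbalance of a real arrhythmia archive
#'
#' Returns per-class counts with proportions 0.84 / 0.026 / 0.067 / 0.007 /
#' 0.074 for N/S/V/F/Q, each rounded as `round(total * p)`. The proportions
#' are applied as stated, so the realised total can differ from `total` by
#' about 1.4%.
#'
#' @param total approximate total number of beats.
#' @return named integer vector of counts for N, S, V, F, Q.
#' @examples
#' imbalanced_class_counts(1000)  # 840 26 67 7 74
#' @export
imbalanced_class_counts <- function(total) {
  p <- c(N = 0.84, S = 0.026, V = 0.067, F = 0.007, Q = 0.074)
  counts <- round(total * p)
  storage.mode(counts) <- "integer"
  counts
}

## fixture format -------------------------------------------------------------

#' Write / read a beat dataset as plain-text fixture files
#'
#' `write_beat_dataset()` persists a dataset as `<prefix>.hdr` (key:value
#' header with the vocabulary, window length, labels and split tags) plus
#' `<prefix>.mat` (whitespace-delimited numeric matrix, one beat per row).
#' `read_beat_dataset()` restores it. `write_beat_csv()` exports one beat per
#' row with the label as last column.
#'
#' @param dataset a `beat_dataset`.
#' @param prefix path prefix for the two fixture files.
#' @param path CSV file path.
#' @return `write_*` return the paths invisibly; `read_beat_dataset` returns
#'   a `beat_dataset`.
#' @export
write_beat_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "beat_dataset"))
  hdr <- c(paste0("n_beats: ", nrow(dataset$X)),
           paste0("window_len: ", ncol(dataset$X)),
           paste0("vocab: ", paste(dataset$vocab, collapse = ",")),
           paste0("labels: ", paste(dataset$labels, collapse = ",")),
           paste0("split: ", paste(dataset$split, collapse = ",")))
  writeLines(hdr, paste0(prefix, ".hdr"))
  utils::write.table(dataset$X, paste0(prefix, ".mat"), row.names = FALSE,
                     col.names = FALSE)
  invisible(c(paste0(prefix, ".hdr"), paste0(prefix, ".mat")))
}

#' @rdname write_beat_dataset
#' @export
read_beat_dataset <- function(prefix) {
  hdr_lines <- readLines(paste0(prefix, ".hdr"))
  get_val <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr_lines, value = TRUE)
    if (!length(ln)) stop_invalid("fixture header missing key: ", key)
    sub(paste0("^", key, ": "), "", ln[1L])
  }
  n <- as.integer(get_val("n_beats"))
  wl <- as.integer(get_val("window_len"))
  vocab <- strsplit(get_val("vocab"), ",")[[1L]]
  labels <- if (n > 0) strsplit(get_val("labels"), ",")[[1L]] else character()
  split <- if (n > 0) strsplit(get_val("split"), ",")[[1L]] else character()
  X <- if (n > 0) {
    as.matrix(utils::read.table(paste0(prefix, ".mat")))
  } else matrix(numeric(), 0L, wl)
  dimnames(X) <- NULL
  stopifnot(nrow(X) == n, ncol(X) == wl)
  beat_dataset(X, labels, vocab = vocab, split = split)
}

#' @rdname write_beat_dataset
#' @export
write_beat_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  df <- as.data.frame(dataset$X)
  names(df) <- paste0("s", seq_len(ncol(dataset$X)))
  df$label <- dataset$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
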