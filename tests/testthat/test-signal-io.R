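test_that("band-pass filter rejects DC, passes mid-band, stops high band", {
  expect_lt(max(abs(bandpass_filter(rep(5, 3600), fs = 360))), 0.05)
  t <- seq(0, 10, by = 1 / 360)
  f10 <- bandpass_filter(sin(2 * pi * 10 * t), fs = 360)
  central <- f10[round(length(t) * 0.1):round(length(t) * 0.9)]
  expect_gte(max(abs(central)), 0.95)
  expect_lte(max(abs(central)), 1.05)
  f120 <- bandpass_filter(sin(2 * pi * 120 * t), fs = 360)
  expect_lt(max(abs(f120)), 0.1)
})

test_that("band-pass filter is linear and rejects bad band edges", {
  set.seed(42)
  a <- rnorm(1000); b <- rnorm(1000)
  lhs <- bandpass_filter(2 * a + 3 * b, fs = 360)
  rhs <- 2 * bandpass_filter(a, fs = 360) + 3 * bandpass_filter(b, fs = 360)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
  expect_error(bandpass_filter(a, fs = 360, low = 50, high = 0.5), "band edges")
  expect_error(bandpass_filter(a, fs = 360, low = 0.5, high = 200), "band edges")
})

test_that("z-score normalization centers, scales, and is idempotent", {
  z <- zscore_normalize(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, c(-1, 0, 1))
  set.seed(5)
  x <- rnorm(200)
  once <- zscore_normalize(x)
  expect_equal(zscore_normalize(once), once, tolerance = 1e-9)
  expect_error(zscore_normalize(c(7, 7, 7)), "constant")
})

test_that("annotation symbols map to the five AAMI classes exactly", {
  expected <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
                A = "S", a = "S", J = "S", S = "S",
                V = "V", E = "V", F = "F", f = "Q", u = "Q")
  for (sym in names(expected))
    expect_identical(map_annotation_symbol(sym), unname(expected[sym]))
  expect_error(map_annotation_symbol("+"), "unmapped")
  expect_error(map_annotation_symbol("~"), "unmapped")
  expect_error(map_annotation_symbol("NN"), "single character")
})

test_that("beat windows are centered and boundary beats are skipped", {
  x <- seq_len(2000)  # signal whose value equals its index
  seg <- segment_beats(x, r_peaks = 1000, symbols = "N", window_len = 360,
                       normalize = FALSE)
  expect_equal(seg$n_segments, 1L)
  expect_equal(as.numeric(seg$dataset$X[1, ]), as.numeric(820:1179))
  near_start <- segment_beats(x, r_peaks = 100, symbols = "N",
                              window_len = 360, normalize = FALSE)
  expect_equal(near_start$n_segments, 0L)
  expect_equal(near_start$n_skipped_boundary, 1L)
  expect_error(segment_beats(seq_len(100), 50, "N", window_len = 360),
               "window_len")
})

test_that("segmentation conserves annotation counts", {
  set.seed(3)
  x <- rnorm(5000)
  r <- c(50, 400, 900, 1500, 2200, 3000, 3600, 4200, 4800, 4990)
  sym <- c("N", "V", "+", "A", "N", "~", "F", "f", "N", "L")
  seg <- segment_beats(x, r, sym, window_len = 360)
  expect_equal(seg$n_segments + seg$n_skipped_boundary + seg$n_skipped_unmapped,
               length(r))
  expect_equal(seg$n_skipped_unmapped, 2L)  # '+' and '~'
  expect_equal(seg$n_skipped_boundary, 2L)  # r = 50 and r = 4990
  expect_equal(seg$dataset$labels, c("V", "S", "N", "F", "Q", "N"))
  interior <- segment_beats(x, seq(500, 4500, length.out = 10), rep("N", 10),
                            window_len = 360)
  expect_equal(interior$n_segments, 10L)
})

test_that("splits hit the 70/10/20 fractions and are deterministic", {
  ds <- generate_dataset(c(N = 100), rng_seed = 1, window_len = 64L)
  ds <- split_dataset(ds, c(0.7, 0.1, 0.2), rng_seed = 5)
  expect_equal(sum(ds$split == "train"), 70L)
  expect_equal(sum(ds$split == "val"), 10L)
  expect_equal(sum(ds$split == "test"), 20L)
  ds2 <- split_dataset(ds, c(0.7, 0.1, 0.2), rng_seed = 5)
  expect_identical(ds$split, ds2$split)
})

test_that("stratified splits round per class by largest remainder", {
  ds <- generate_dataset(c(N = 10, V = 10), rng_seed = 2, window_len = 64L)
  ds <- split_dataset(ds, c(0.7, 0.1, 0.2), rng_seed = 3, stratified = TRUE)
  for (cl in c("N", "V")) {
    tab <- table(factor(ds$split[ds$labels == cl],
                        levels = c("train", "val", "test")))
    expect_equal(unname(as.integer(tab)), c(7L, 1L, 2L))
  }
})

test_that("splits partition every dataset for every seed tried", {
  ds <- generate_dataset(c(N = 37, S = 11, V = 23), rng_seed = 8,
                         window_len = 64L)
  for (seed in 1:5) {
    sp <- split_dataset(ds, rng_seed = seed)
    expect_true(all(sp$split %in% c("train", "val", "test")))
    expect_equal(length(sp$split), nrow(ds$X))
    per_class <- table(sp$labels, sp$split)
    expect_equal(rowSums(per_class), table(ds$labels)[rownames(per_class)],
                 ignore_attr = TRUE)
  }
})

test_that("a tiny class is kept whole in train with a warning", {
  ds <- generate_dataset(c(N = 30, F = 2), rng_seed = 4, window_len = 64L)
  expect_warning(sp <- split_dataset(ds, rng_seed = 1, stratified = TRUE),
                 "kept whole")
  expect_true(all(sp$split[sp$labels == "F"] == "train"))
})

test_that("augmentation identity, scaling and stretching behave as stated", {
  tpl <- default_beat_templates(noise_sd = 0, jitter_sd = 0)$N
  beat <- as.numeric(generate_beat(tpl, window_len = 360L, rng_seed = 1))
  expect_equal(augment_beat(beat, 1, 1), beat, tolerance = 1e-9)
  expect_equal(augment_beat(beat, 1, 2), 2 * beat, tolerance = 1e-9)
  expect_error(augment_beat(beat, 0.2, 1), "stretch")
  expect_error(augment_beat(beat, 1, -1), "scale")

  ## single Gaussian of width w, stretched 1.5x: fitted width within 10%
  w <- 0.05
  t_grid <- seq(0, 1, length.out = 360)
  bump <- exp(-(t_grid - 0.5)^2 / (2 * w^2))
  stretched <- augment_beat(bump, 1.5, 1)
  fit <- nls(y ~ exp(-(t_grid - mu)^2 / (2 * sigma^2)),
             data = data.frame(y = stretched, t_grid = t_grid),
             start = list(mu = 0.5, sigma = w))
  expect_lt(abs(coef(fit)[["sigma"]] - 1.5 * w) / (1.5 * w), 0.1)
})

test_that("dataset augmentation touches only minority training beats", {
  ds <- generate_dataset(c(N = 20, V = 10), rng_seed = 6, window_len = 64L)
  ds <- split_dataset(ds, rng_seed = 2)
  n_v_train <- sum(ds$split == "train" & ds$labels == "V")
  aug <- augment_dataset(ds, classes = "V", rng_seed = 3)
  expect_equal(nrow(aug$X), nrow(ds$X) + n_v_train)
  expect_true(all(aug$split[-seq_len(nrow(ds$X))] == "train"))
  expect_true(all(aug$labels[-seq_len(nrow(ds$X))] == "V"))
  expect_identical(aug$X[seq_len(nrow(ds$X)), ], ds$X)
})
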