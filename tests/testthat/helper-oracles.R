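## Independent brute-force oracles used to pin down expected values.
## These deliberately avoid the package's vectorized code paths.

## y_t = sum_k w_k x_{t-k+1} + bias, double loop over valid positions
oracle_conv1d <- function(x, w, bias = 0) {
  K <- length(w)
  out <- numeric(length(x) - K + 1)
  for (t in K:length(x)) {
    acc <- bias
    for (k in seq_len(K)) acc <- acc + w[k] * x[t - k + 1]
    out[t - K + 1] <- acc
  }
  out
}

## softmax(Q K' / sqrt(d_k)) V via explicit per-row exp/sum loops
oracle_attention <- function(Q, K, V, mask = NULL) {
  dk <- ncol(K)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    logits <- numeric(nrow(K))
    for (j in seq_len(nrow(K)))
      logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    if (!is.null(mask)) logits[!mask] <- -Inf
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

## per-class metrics recounted directly from the raw label lists
oracle_metrics <- function(y_true, y_pred, vocab) {
  n <- length(y_true)
  per <- lapply(vocab, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(accuracy = (tp + tn) / n,
         precision = prec, recall = rec,
         specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
         f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  })
  names(per) <- vocab
  per
}

## smallest full model configuration used across the unit tests
tiny_config <- function(...) {
  defaults <- list(vocab = c("A", "B", "C"), window_len = 40L,
                   channels = c(2L, 3L), kernel_size = 3L, pool_window = 2L,
                   conv_dropout = 0, cnn_out_len = 4L, cnn_out_dim = 5L,
                   d_model = 6L, n_layers = 1L, n_heads = 2L,
                   d_k = 3L, d_v = 3L, d_inner = 7L, encoder_dropout = 0,
                   fusion_d = 6L, fusion_heads = 2L,
                   gamma = 2, alpha = "uniform", lr_max = 1e-3,
                   batch_size = 8L, max_epochs = 3L, patience = 2L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

## small well-separated two-class dataset on the tiny window
tiny_dataset <- function(n_per_class = 12L, window_len = 40L, seed = 11L,
                         noise_sd = 0.02) {
  waves <- data.frame(center = c(0.2, 0.4, 0.5, 0.6, 0.8),
                      width = c(0.04, 0.02, 0.03, 0.02, 0.06),
                      amplitude = c(0.2, -0.1, 1, -0.2, 0.3),
                      row.names = c("P", "Q", "R", "S", "T"))
  waves_b <- waves; waves_b["R", "width"] <- 0.09; waves_b["P", "amplitude"] <- 0
  tpls <- list(A = beat_template("A", waves, noise_sd = noise_sd),
               B = beat_template("B", waves_b, noise_sd = noise_sd))
  generate_dataset(stats::setNames(rep(n_per_class, 2), c("A", "B")),
                   tpls, window_len = window_len, rng_seed = seed)
}
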