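## Global sequence modeling: convolutional embedding into the model space,
## learned positional encodings, a learned [CLS] summary token, stacked
## pre-LayerNorm transformer encoder layers with padding masks, and a
## trailing lightweight (depthwise) convolution.

#' Transformer encoder configuration
#'
#' @param n_layers number of encoder layers (default 4).
#' @param n_heads attention heads per layer (default 4).
#' @param d_model embedding dimension (default 256).
#' @param d_k,d_v per-head key/query and value dimensions (default 64).
#' @param d_inner feed-forward hidden dimension (default `2 * d_model`).
#' @param dropout_rate dropout probability (default 0.1).
#' @param max_len maximum sequence length including the [CLS] position.
#' @param embed_kernel kernel width of the input convolutional embedding.
#' @param trailing_kernel kernel width of the trailing depthwise convolution.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 4L, n_heads = 4L, d_model = 256L,
                           d_k = 64L, d_v = 64L, d_inner = 2L * d_model,
                           dropout_rate = 0.1, max_len = 64L,
                           embed_kernel = 3L, trailing_kernel = 3L) {
  if (d_model < 1 || n_layers < 1 || n_heads < 1 || d_k < 1 || d_v < 1)
    stop_config("encoder dimensions must be positive")
  if (embed_kernel %% 2 == 0 || trailing_kernel %% 2 == 0)
    stop_config("embedding/trailing kernels must be odd")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_k = as.integer(d_k),
                 d_v = as.integer(d_v), d_inner = as.integer(d_inner),
                 dropout_rate = dropout_rate, max_len = as.integer(max_len),
                 embed_kernel = as.integer(embed_kernel),
                 trailing_kernel = as.integer(trailing_kernel)),
            class = "encoder_config")
}

#' Learned positional-encoding table
#'
#' One trainable `d_model`-vector per position, initialized from small
#' Gaussian draws under the current RNG state; the table is added
#' elementwise to the embedded sequence.
#'
#' @param max_len number of positions.
#' @param d_model embedding dimension.
#' @param sd initialization scale (default 0.02).
#' @return `max_len` x `d_model` matrix.
#' @export
positional_encoding <- function(max_len, d_model, sd = 0.02) {
  if (max_len < 1 || d_model < 1) stop_invalid("max_len and d_model must be >= 1")
  matrix(stats::rnorm(max_len * d_model, 0, sd), max_len, d_model)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, assigning masked keys a `-Inf`
#' logit so they receive zero weight.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` share the last dimension
#'   `d_k`, `K` and `V` share the number of rows (keys).
#' @param mask optional logical vector of key validity flags.
#' @return attention output matrix (`nrow(Q)` x `ncol(V)`).
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K)) stop_invalid("Q and K must share their last dimension")
  if (nrow(K) != nrow(V)) stop_invalid("K and V must share their key count")
  if (!is.null(mask) && !any(mask))
    stop_degenerate("all keys are masked for every query")
  attention_fw(Q, K, V, mask)$y
}

## parameter initialization ---------------------------------------------------

init_mha_params <- function(cfg) {
  d <- cfg$d_model; h <- cfg$n_heads
  list(Wq = kaiming_uniform(d, h * cfg$d_k), bq = numeric(h * cfg$d_k),
       Wk = kaiming_uniform(d, h * cfg$d_k), bk = numeric(h * cfg$d_k),
       Wv = kaiming_uniform(d, h * cfg$d_v), bv = numeric(h * cfg$d_v),
       Wo = kaiming_uniform(h * cfg$d_v, d), bo = numeric(d))
}

init_encoder_layer_params <- function(cfg) {
  d <- cfg$d_model
  list(ln1 = list(g = rep(1, d), b = numeric(d)),
       mha = init_mha_params(cfg),
       ln2 = list(g = rep(1, d), b = numeric(d)),
       ffn = list(W1 = kaiming_uniform(d, cfg$d_inner), b1 = numeric(cfg$d_inner),
                  W2 = kaiming_uniform(cfg$d_inner, d), b2 = numeric(d)))
}

init_bert_params <- function(cfg, d_in) {
  list(emb = list(W = kaiming_uniform(cfg$embed_kernel * d_in, cfg$d_model),
                  b = numeric(cfg$d_model)),
       cls = stats::rnorm(cfg$d_model, 0, 0.02),
       pos = positional_encoding(cfg$max_len, cfg$d_model),
       layers = lapply(seq_len(cfg$n_layers),
                       function(i) init_encoder_layer_params(cfg)),
       lnf = list(g = rep(1, cfg$d_model), b = numeric(cfg$d_model)),
       trail = list(W = matrix(stats::rnorm(cfg$trailing_kernel * cfg$d_model, 0,
                                            1 / sqrt(cfg$trailing_kernel)),
                               cfg$trailing_kernel, cfg$d_model),
                    b = numeric(cfg$d_model)))
}

## multi-head attention -------------------------------------------------------

mha_fw <- function(x, pw, cfg, mask = NULL) {
  h <- cfg$n_heads; dk <- cfg$d_k; dv <- cfg$d_v
  q_lin <- linear_fw(x, pw$Wq, pw$bq)
  k_lin <- linear_fw(x, pw$Wk, pw$bk)
  v_lin <- linear_fw(x, pw$Wv, pw$bv)
  heads <- vector("list", h)
  concat <- matrix(0, nrow(x), h * dv)
  for (i in seq_len(h)) {
    qi <- ((i - 1L) * dk + 1L):(i * dk)
    vi <- ((i - 1L) * dv + 1L):(i * dv)
    att <- attention_fw(q_lin$y[, qi, drop = FALSE],
                        k_lin$y[, qi, drop = FALSE],
                        v_lin$y[, vi, drop = FALSE], mask)
    concat[, vi] <- att$y
    heads[[i]] <- att$cache
  }
  o_lin <- linear_fw(concat, pw$Wo, pw$bo)
  list(y = o_lin$y,
       cache = list(q = q_lin$cache, k = k_lin$cache, v = v_lin$cache,
                    heads = heads, o = o_lin$cache, h = h, dk = dk, dv = dv))
}

mha_bw <- function(dy, cache) {
  ob <- linear_bw(dy, cache$o)
  dconcat <- ob$dx
  h <- cache$h; dk <- cache$dk; dv <- cache$dv
  Tn <- nrow(dconcat)
  dQall <- matrix(0, Tn, h * dk); dKall <- matrix(0, Tn, h * dk)
  dVall <- matrix(0, Tn, h * dv)
  for (i in seq_len(h)) {
    qi <- ((i - 1L) * dk + 1L):(i * dk)
    vi <- ((i - 1L) * dv + 1L):(i * dv)
    ab <- attention_bw(dconcat[, vi, drop = FALSE], cache$heads[[i]])
    dQall[, qi] <- ab$dQ; dKall[, qi] <- ab$dK; dVall[, vi] <- ab$dV
  }
  qb <- linear_bw(dQall, cache$q)
  kb <- linear_bw(dKall, cache$k)
  vb <- linear_bw(dVall, cache$v)
  list(dx = qb$dx + kb$dx + vb$dx,
       grads = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                    Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db))
}

## pre-LayerNorm encoder layer ------------------------------------------------

encoder_layer_fw <- function(x, pw, cfg, mask = NULL, train = FALSE) {
  ln1 <- layernorm_fw(x, pw$ln1$g, pw$ln1$b)
  att <- mha_fw(ln1$y, pw$mha, cfg, mask)
  dr1 <- dropout_fw(att$y, cfg$dropout_rate, train)
  u <- x + dr1$y
  ln2 <- layernorm_fw(u, pw$ln2$g, pw$ln2$b)
  f1 <- linear_fw(ln2$y, pw$ffn$W1, pw$ffn$b1)
  ac <- relu_fw(f1$y)
  f2 <- linear_fw(ac$y, pw$ffn$W2, pw$ffn$b2)
  dr2 <- dropout_fw(f2$y, cfg$dropout_rate, train)
  list(y = u + dr2$y,
       cache = list(ln1 = ln1$cache, att = att$cache, dr1 = dr1$cache,
                    ln2 = ln2$cache, f1 = f1$cache, ac = ac$cache,
                    f2 = f2$cache, dr2 = dr2$cache))
}

encoder_layer_bw <- function(dy, cache) {
  d_f2 <- dropout_bw(dy, cache$dr2)
  f2b <- linear_bw(d_f2, cache$f2)
  acb <- relu_bw(f2b$dx, cache$ac)
  f1b <- linear_bw(acb, cache$f1)
  ln2b <- layernorm_bw(f1b$dx, cache$ln2)
  du <- dy + ln2b$dx
  d_att <- dropout_bw(du, cache$dr1)
  ab <- mha_bw(d_att, cache$att)
  ln1b <- layernorm_bw(ab$dx, cache$ln1)
  list(dx = du + ln1b$dx,
       grads = list(ln1 = list(g = ln1b$dg, b = ln1b$db),
                    mha = ab$grads,
                    ln2 = list(g = ln2b$dg, b = ln2b$db),
                    ffn = list(W1 = f1b$dW, b1 = f1b$db,
                               W2 = f2b$dW, b2 = f2b$db)))
}

#' Multi-head self-attention over a feature sequence
#'
#' Projects the sequence to per-head query/key/value spaces, runs
#' [scaled_dot_attention()] per head, concatenates the head outputs and
#' projects back to `d_model`.
#'
#' @param x `T` x `d_model` feature sequence.
#' @param config an [encoder_config()].
#' @param weights parameter set (from the internal initializer); if `NULL`,
#'   initialized from the current RNG state.
#' @param mask optional key-validity flags (length `T`).
#' @return `T` x `d_model` output sequence.
#' @export
multi_head_attention <- function(x, config, weights = NULL, mask = NULL) {
  if (ncol(x) != config$d_model)
    stop_config("input feature dimension must equal d_model")
  if (is.null(weights)) weights <- init_mha_params(config)
  mha_fw(x, weights, config, mask)$y
}

#' One transformer encoder layer (pre-LayerNorm)
#'
#' `x + MHA(LN(x))` followed by `(.) + FFN(LN(.))`, with dropout inside each
#' residual branch when `train_mode` is on. The feed-forward network is
#' `linear(d_model -> d_inner) -> ReLU -> linear(d_inner -> d_model)`.
#'
#' @inheritParams multi_head_attention
#' @param train_mode enable dropout.
#' @return `T` x `d_model` output sequence.
#' @export
encoder_layer <- function(x, config, weights = NULL, mask = NULL,
                          train_mode = FALSE) {
  if (ncol(x) != config$d_model)
    stop_config("input feature dimension must equal d_model")
  if (is.null(weights)) weights <- init_encoder_layer_params(config)
  encoder_layer_fw(x, weights, config, mask, train_mode)$y
}

## full encoder ---------------------------------------------------------------

bert_fw_one <- function(C, params, cfg, mask = NULL, train = FALSE) {
  Tn <- nrow(C)
  if (Tn + 1L > cfg$max_len) stop_invalid("sequence longer than max_len")
  if (is.null(mask)) mask <- rep(TRUE, Tn)
  emb <- conv_same_fw(C, params$emb$W, params$emb$b, cfg$embed_kernel)
  x <- rbind(params$cls, emb$y) + params$pos[seq_len(Tn + 1L), , drop = FALSE]
  full_mask <- c(TRUE, mask)
  dr <- dropout_fw(x, cfg$dropout_rate, train)
  x <- dr$y
  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lf <- encoder_layer_fw(x, params$layers[[l]], cfg, full_mask, train)
    x <- lf$y
    layer_caches[[l]] <- lf$cache
  }
  lnf <- layernorm_fw(x, params$lnf$g, params$lnf$b)
  H <- lnf$y
  summary_vec <- H[1L, ]
  body <- H[-1L, , drop = FALSE]
  trail <- depthwise_same_fw(body, params$trail$W, params$trail$b,
                             cfg$trailing_kernel)
  B <- trail$y
  B[!mask, ] <- 0
  list(B = B, summary = summary_vec,
       cache = list(emb = emb$cache, dr = dr$cache, layers = layer_caches,
                    lnf = lnf$cache, trail = trail$cache, Tn = Tn, mask = mask))
}

bert_bw_one <- function(dB, dsummary, cache, params, cfg) {
  dB[!cache$mask, ] <- 0
  tb <- depthwise_same_bw(dB, cache$trail)
  dH <- rbind(dsummary, tb$dx)
  lnfb <- layernorm_bw(dH, cache$lnf)
  dx <- lnfb$dx
  layer_grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- encoder_layer_bw(dx, cache$layers[[l]])
    dx <- lb$dx
    layer_grads[[l]] <- lb$grads
  }
  dx <- dropout_bw(dx, cache$dr)
  dcls <- dx[1L, ]
  dpos <- matrix(0, nrow(params$pos), ncol(params$pos))
  dpos[seq_len(cache$Tn + 1L), ] <- dx
  eb <- conv_same_bw(dx[-1L, , drop = FALSE], cache$emb)
  list(dC = eb$dx,
       grads = list(emb = list(W = eb$dW, b = eb$db),
                    cls = dcls, pos = dpos, layers = layer_grads,
                    lnf = list(g = lnfb$dg, b = lnfb$db),
                    trail = list(W = tb$dW, b = tb$db)))
}

#' Encode a feature sequence with the transformer stack
#'
#' Applies the input convolutional embedding (same padding, projecting the
#' CNN feature dimension into the model space), prepends the learned [CLS]
#' vector, adds positional encodings, runs the stacked encoder layers under
#' the padding mask, and returns the encoded body sequence after the
#' trailing lightweight (depthwise) convolution together with the [CLS]
#' output as the sequence summary. Masked positions carry zero output and
#' receive no attention.
#'
#' @param features `T` x `d_in` feature sequence (e.g. from [cnn_forward()]);
#'   a logical `mask` attribute marks valid time steps (default all valid).
#' @param config an [encoder_config()].
#' @param weights parameter set; if `NULL`, initialized from the current RNG
#'   state for the given input dimension.
#' @param train_mode enable dropout.
#' @return list with `encoded` (`T` x `d_model` matrix) and `summary`
#'   (`d_model` vector from the [CLS] position).
#' @export
bert_forward <- function(features, config, weights = NULL, train_mode = FALSE) {
  mask <- attr(features, "mask") %||% rep(TRUE, nrow(features))
  if (is.null(weights)) weights <- init_bert_params(config, ncol(features))
  out <- bert_fw_one(features, weights, config, mask, train_mode)
  list(encoded = out$B, summary = out$summary)
}
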