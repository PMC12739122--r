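## Full model: CNN front end -> transformer encoder -> cross-modal gated
## fusion -> softmax classification head, with a single nested parameter
## set and explicit forward/backward passes.

#' Build a full model configuration
#'
#' Collects every architectural hyperparameter. Defaults follow the
#' full-size architecture (three conv blocks 16/32/64, four encoder layers
#' with four heads and `d_model = 256`); [reduced_model_config()] gives the
#' small configuration used for CPU-scale experiments.
#'
#' @param vocab ordered class vocabulary.
#' @param window_len beat window length in samples.
#' @param channels output channels of the successive conv blocks.
#' @param kernel_size,pool_window,conv_dropout conv block settings.
#' @param cnn_out_len,cnn_out_dim shape `T` x `d_c` of the CNN feature
#'   sequence.
#' @param d_model,n_layers,n_heads,d_k,d_v,d_inner,encoder_dropout
#'   transformer settings (see [encoder_config()]).
#' @param fusion_d,fusion_heads shared fusion dimension `d` and head count.
#' @param gamma,alpha focal-loss settings: focusing exponent and per-class
#'   weights (`"inverse_frequency"`, `"uniform"`, or a positive vector).
#' @param lr_max,warmup_frac,batch_size,max_epochs,patience training-loop
#'   settings; `warmup_frac` is the warm-up fraction of total steps.
#' @param two_stage if `TRUE`, [train_model()] freezes both encoders and
#'   trains only fusion + head.
#' @return object of class `model_config`.
#' @export
model_config <- function(vocab = c("N", "S", "V", "F", "Q"),
                         window_len = 360L,
                         channels = c(16L, 32L, 64L),
                         kernel_size = 3L, pool_window = 2L,
                         conv_dropout = 0.3,
                         cnn_out_len = 16L, cnn_out_dim = 64L,
                         d_model = 256L, n_layers = 4L, n_heads = 4L,
                         d_k = 64L, d_v = 64L, d_inner = 2L * d_model,
                         encoder_dropout = 0.1,
                         fusion_d = d_model, fusion_heads = n_heads,
                         gamma = 2, alpha = "inverse_frequency",
                         lr_max = 1e-3, warmup_frac = 0.08,
                         batch_size = 64L, max_epochs = 50L, patience = 5L,
                         two_stage = FALSE) {
  in_ch <- c(1L, channels[-length(channels)])
  specs <- lapply(seq_along(channels), function(i)
    conv_spec(in_ch[i], channels[i], kernel_size, pool_window, conv_dropout))
  enc <- encoder_config(n_layers, n_heads, d_model, d_k, d_v, d_inner,
                        encoder_dropout, max_len = cnn_out_len + 1L)
  fus <- fusion_config(d_c = cnn_out_dim, d_b = d_model,
                       d = fusion_d, h = fusion_heads)
  if (length(vocab) < 2) stop_config("at least two classes required")
  structure(list(vocab = vocab, class_num = length(vocab),
                 window_len = as.integer(window_len), specs = specs,
                 cnn_out_len = as.integer(cnn_out_len),
                 cnn_out_dim = as.integer(cnn_out_dim),
                 encoder = enc, fusion = fus,
                 gamma = gamma, alpha = alpha,
                 lr_max = lr_max, warmup_frac = warmup_frac,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 two_stage = isTRUE(two_stage)),
            class = "model_config")
}

#' Reduced configuration for single-CPU experiments
#'
#' Two conv blocks (8, 16 channels), two encoder layers with two heads and
#' `d_model = 32`; the architecture is unchanged, only narrower and
#' shallower.
#'
#' @param ... overrides passed on to [model_config()].
#' @export
reduced_model_config <- function(...) {
  defaults <- list(channels = c(8L, 16L), cnn_out_len = 16L, cnn_out_dim = 32L,
                   d_model = 32L, n_layers = 2L, n_heads = 2L,
                   d_k = 16L, d_v = 16L, d_inner = 64L,
                   fusion_d = 32L, fusion_heads = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Initialize all model parameters
#'
#' Conv and linear weights are Kaiming-uniform, biases zero, positional and
#' [CLS] embeddings small Gaussian, LayerNorm gain 1 / bias 0.
#'
#' @param config a [model_config()].
#' @param rng_seed integer seed.
#' @return nested parameter list (class `model_params`).
#' @export
init_model <- function(config, rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  init_model_with_current_rng(config)
}

## forward pass for one beat; returns class probabilities and all caches
model_fw_one <- function(beat, params, config, train = FALSE) {
  cnn <- cnn_fw_one(beat, config$specs, params$cnn,
                    config$cnn_out_len, config$cnn_out_dim, train)
  bert <- bert_fw_one(cnn$C, params$bert, config$encoder, train = train)
  proj_c <- linear_fw(cnn$C, params$fusion$Wc, params$fusion$bc)
  proj_b <- linear_fw(bert$B, params$fusion$Wb, params$fusion$bb)
  xatt <- cross_attention_fw(proj_c$y, proj_b$y, params$fusion, config$fusion)
  gate <- gated_fusion_fw(proj_c$y, xatt$y, params$fusion)
  cls <- classify_fw(gate$y, bert$summary, params$head)
  list(probs = cls$probs,
       cache = list(cnn = cnn$cache, bert = bert$cache,
                    proj_c = proj_c$cache, proj_b = proj_b$cache,
                    xatt = xatt$cache, gate = gate$cache, cls = cls$cache))
}

## backward pass from a logit gradient dz for one beat
model_bw_one <- function(dz, cache, params, config) {
  cb <- classify_bw(dz, cache$cls)
  gb <- gated_fusion_bw(cb$dF, cache$gate, params$fusion)
  xb <- cross_attention_bw(gb$dFcb, cache$xatt, params$fusion)
  dCp <- gb$dCp + xb$dCp
  pcb <- linear_bw(dCp, cache$proj_c)
  pbb <- linear_bw(xb$dBp, cache$proj_b)
  bb <- bert_bw_one(pbb$dx, cb$dsummary, cache$bert, params$bert, config$encoder)
  dC <- pcb$dx + bb$dC
  cnnb <- cnn_bw_one(dC, cache$cnn, config$specs)
  list(grads = list(
    cnn = cnnb$grads,
    bert = bb$grads,
    fusion = list(Wc = pcb$dW, bc = pcb$db, Wb = pbb$dW, bb = pbb$db,
                  Wq = xb$grads$Wq, Wk = xb$grads$Wk, Wv = xb$grads$Wv,
                  Wg = gb$grads$Wg, bg = gb$grads$bg),
    head = cb$grads))
}

## mean focal loss and parameter gradients over a batch
batch_loss_grads <- function(params, X, y_idx, config, alpha_vec,
                             train = TRUE, compute_grads = TRUE) {
  n <- nrow(X)
  total_loss <- 0
  grads <- if (compute_grads) zeros_like(unclass(params)) else NULL
  correct <- 0L
  for (i in seq_len(n)) {
    fw <- model_fw_one(X[i, ], params, config, train)
    fl <- focal_loss_grad(fw$probs, y_idx[i], config$gamma, alpha_vec)
    total_loss <- total_loss + fl$loss
    if (which.max(fw$probs) == y_idx[i]) correct <- correct + 1L
    if (compute_grads) {
      bw <- model_bw_one(fl$dz / n, fw$cache, params, config)
      grads <- add_params(grads, bw$grads)
    }
  }
  list(loss = total_loss / n, grads = grads, accuracy = correct / n)
}

#' Predict class labels and probabilities for a beat matrix
#'
#' @param object a trained model from [train_model()], or a list with
#'   `params` and `config`.
#' @param newdata numeric beat matrix (one beat per row) or a
#'   [beat_dataset()].
#' @param ... unused.
#' @return list with `labels` (character) and `probs` (matrix, one row per
#'   beat, columns in vocabulary order).
#' @export
predict.beatformer_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "beat_dataset")) newdata$X else as.matrix(newdata)
  probs <- matrix(0, nrow(X), object$config$class_num)
  for (i in seq_len(nrow(X)))
    probs[i, ] <- model_fw_one(X[i, ], object$params, object$config,
                               train = FALSE)$probs
  colnames(probs) <- object$config$vocab
  list(labels = object$config$vocab[max.col(probs, ties.method = "first")],
       probs = probs)
}
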