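## Supervised training: focal loss, warm-up / inverse-square-root learning
## rate schedule, Adam, early stopping and checkpointing.

#' Focal-loss settings
#'
#' @param gamma focusing exponent, `>= 0`; `gamma = 0` reduces the loss to
#'   weighted cross-entropy.
#' @param alpha per-class weight vector (positive entries), a single
#'   positive number applied to all classes, or `"uniform"`.
#' @return object of class `focal_loss_spec`.
#' @export
focal_loss_spec <- function(gamma = 2, alpha = "uniform") {
  if (gamma < 0) stop_invalid("gamma must be >= 0")
  if (is.numeric(alpha) && any(alpha <= 0))
    stop_invalid("alpha entries must be positive")
  structure(list(gamma = gamma, alpha = alpha), class = "focal_loss_spec")
}

resolve_alpha <- function(alpha, class_idx) {
  if (is.character(alpha)) return(1)
  if (length(alpha) == 1L) return(alpha)
  alpha[class_idx]
}

#' Focal loss of one prediction
#'
#' `FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)`, where `p_t` is the
#' predicted probability of the true class and `alpha_t` its class weight.
#' A zero `p_t` is clamped to `1e-12` with a warning so the loss stays
#' finite. The batch loss used in training is the mean over samples.
#'
#' @param probabilities per-class probability vector summing to 1.
#' @param true_class index (1-based) of the true class.
#' @param spec a [focal_loss_spec()].
#' @return nonnegative scalar loss.
#' @examples
#' focal_loss(c(0.5, 0.5), 1, focal_loss_spec(gamma = 0))  # log(2)
#' @export
focal_loss <- function(probabilities, true_class, spec = focal_loss_spec()) {
  if (abs(sum(probabilities) - 1) > 1e-6 || any(probabilities < 0))
    stop_invalid("probabilities must be a valid simplex point")
  p_t <- probabilities[true_class]
  if (p_t <= 0) {
    warning("true-class probability is 0; clamped to 1e-12")
    p_t <- 1e-12
  }
  a_t <- resolve_alpha(spec$alpha, true_class)
  -a_t * (1 - p_t)^spec$gamma * log(p_t)
}

## loss plus gradient w.r.t. the logits that produced `probs` via softmax
focal_loss_grad <- function(probs, true_class, gamma, alpha_vec) {
  p_t <- max(probs[true_class], 1e-12)
  a_t <- resolve_alpha(alpha_vec, true_class)
  one_m <- 1 - p_t
  loss <- -a_t * one_m^gamma * log(p_t)
  ## dL/dp_t, then through the softmax jacobian (L depends only on p_t)
  dL_dpt <- if (gamma == 0) -a_t / p_t else
    a_t * (gamma * one_m^(gamma - 1) * log(p_t) - one_m^gamma / p_t)
  dz <- -dL_dpt * p_t * probs
  dz[true_class] <- dz[true_class] + dL_dpt * p_t
  list(loss = loss, dz = dz)
}

#' Learning-rate schedule settings
#'
#' @param lr_max peak learning rate reached at the end of warm-up.
#' @param warmup_steps number of warm-up steps, `1 <= warmup_steps <=
#'   total_steps`.
#' @param total_steps total optimizer steps of the run.
#' @return object of class `schedule_spec`.
#' @export
schedule_spec <- function(lr_max, warmup_steps, total_steps) {
  if (warmup_steps < 1 || warmup_steps > total_steps)
    stop_invalid("need 1 <= warmup_steps <= total_steps")
  structure(list(lr_max = lr_max, warmup_steps = warmup_steps,
                 total_steps = total_steps), class = "schedule_spec")
}

#' Learning rate at a given optimizer step
#'
#' `lr = lr_max * min(step / warmup_steps, sqrt(warmup_steps / step))`:
#' linear warm-up to `lr_max`, then inverse-square-root decay. Both branches
#' equal `lr_max` exactly at `step = warmup_steps`.
#'
#' @param step 1-based optimizer step.
#' @param spec a [schedule_spec()].
#' @return the learning rate.
#' @export
lr_at_step <- function(step, spec) {
  if (any(step < 1)) stop_invalid("the schedule is 1-based: step >= 1")
  spec$lr_max * pmin(step / spec$warmup_steps, sqrt(spec$warmup_steps / step))
}

## Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

## per-beat z-scoring of a whole dataset
#' Z-score every beat of a dataset
#'
#' @param dataset a [beat_dataset()].
#' @return the dataset with each beat normalized by [zscore_normalize()].
#' @export
normalize_beats <- function(dataset) {
  dataset$X <- t(apply(dataset$X, 1L, zscore_normalize))
  dataset
}

inverse_frequency_alpha <- function(labels, vocab) {
  counts <- table(factor(labels, levels = vocab))
  counts[counts == 0] <- 1  # absent classes get a neutral weight
  inv <- 1 / as.numeric(counts)
  inv / mean(inv)
}

#' Train the full model
#'
#' Runs Adam with the warm-up / inverse-square-root schedule over mini
#' batches of the training split, computes validation loss and macro-F1
#' after every epoch, keeps the best-performing weights (by validation
#' macro-F1), and stops early once `patience` epochs pass without
#' improvement. All randomness (initialization, shuffling, dropout) derives
#' from `rng_seed`, so a fixed seed reproduces the run exactly.
#'
#' @param dataset a [beat_dataset()] with nonempty `train` and `val` splits
#'   (beats already preprocessed/normalized as desired).
#' @param config a [model_config()].
#' @param rng_seed integer seed.
#' @param checkpoint_path optional RDS path; the best weights are saved there
#'   whenever validation macro-F1 improves.
#' @param verbose print one line per epoch.
#' @param val_metric_fn advanced hook: function(epoch, metrics_report) used
#'   in place of validation macro-F1 as the selection metric.
#' @param stop_train_acc optional threshold in `(0, 1]`: stop once the
#'   epoch's training accuracy reaches it (used for memorization checks).
#' @return object of class `beatformer_model`: best `params` (by validation
#'   metric), `final_params` (last epoch), `config`, per-epoch `history`
#'   data frame, `best_epoch`, `vocab`, and the final training `state`
#'   (epoch, step, best metric, epochs since improvement).
#' @export
train_model <- function(dataset, config, rng_seed = 1L,
                        checkpoint_path = NULL, verbose = FALSE,
                        val_metric_fn = NULL, stop_train_acc = NULL) {
  stopifnot(inherits(dataset, "beat_dataset"))
  tr_idx <- which(dataset$split == "train")
  va_idx <- which(dataset$split == "val")
  if (!length(tr_idx) || !length(va_idx))
    stop_config("dataset needs nonempty train and val splits")
  vocab <- config$vocab
  if (!all(dataset$labels %in% vocab))
    stop_config("dataset labels outside the configured vocabulary")
  set.seed(as.integer(rng_seed))
  params <- unclass(init_model_with_current_rng(config))
  if (identical(config$alpha, "inverse_frequency")) {
    alpha_vec <- inverse_frequency_alpha(dataset$labels[tr_idx], vocab)
  } else if (identical(config$alpha, "uniform")) {
    alpha_vec <- rep(1, config$class_num)
  } else alpha_vec <- config$alpha

  y_idx <- match(dataset$labels, vocab)
  Xtr <- dataset$X[tr_idx, , drop = FALSE]; ytr <- y_idx[tr_idx]
  Xva <- dataset$X[va_idx, , drop = FALSE]; yva <- y_idx[va_idx]

  steps_per_epoch <- max(1L, ceiling(length(tr_idx) / config$batch_size))
  total_steps <- steps_per_epoch * config$max_epochs
  sched <- schedule_spec(config$lr_max,
                         max(1L, round(config$warmup_frac * total_steps)),
                         total_steps)
  opt <- adam_init(params)
  frozen <- if (config$two_stage) c("cnn", "bert") else character(0)

  history <- data.frame()
  best_metric <- -Inf; best_params <- params; best_epoch <- 0L
  since_improvement <- 0L; global_step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(length(ytr))
    epoch_loss <- 0; n_seen <- 0L; n_correct <- 0L
    for (start in seq(1L, length(perm), by = config$batch_size)) {
      bidx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
      res <- batch_loss_grads(params, Xtr[bidx, , drop = FALSE], ytr[bidx],
                              config, alpha_vec, train = TRUE)
      if (!is.finite(res$loss))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      grads <- res$grads
      for (blk in frozen) grads[[blk]] <- zeros_like(params[[blk]])
      global_step <- global_step + 1L
      upd <- adam_step(params, grads, opt, lr_at_step(global_step, sched))
      params <- upd$params; opt <- upd$state
      epoch_loss <- epoch_loss + res$loss * length(bidx)
      n_correct <- n_correct + round(res$accuracy * length(bidx))
      n_seen <- n_seen + length(bidx)
    }
    val <- batch_loss_grads(params, Xva, yva, config, alpha_vec,
                            train = FALSE, compute_grads = FALSE)
    val_pred <- character(nrow(Xva))
    for (i in seq_len(nrow(Xva)))
      val_pred[i] <- vocab[which.max(
        model_fw_one(Xva[i, ], params, config, train = FALSE)$probs)]
    report <- compute_metrics(confusion_matrix(vocab[yva], val_pred, vocab))
    metric <- if (is.null(val_metric_fn)) report$aggregate$macro_f1 else
      val_metric_fn(epoch, report)
    history <- rbind(history, data.frame(
      epoch = epoch, step = global_step,
      lr = lr_at_step(global_step, sched),
      train_loss = epoch_loss / n_seen,
      train_accuracy = n_correct / n_seen, val_loss = val$loss,
      val_accuracy = val$accuracy, val_macro_f1 = report$aggregate$macro_f1,
      selection_metric = metric))
    if (verbose)
      message(sprintf(
        "epoch %d  step %d  lr %.2e  train_loss %.4f  val_loss %.4f  val_acc %.3f  val_macroF1 %.3f",
        epoch, global_step, lr_at_step(global_step, sched),
        epoch_loss / n_seen, val$loss, val$accuracy,
        report$aggregate$macro_f1))
    if (metric > best_metric) {
      best_metric <- metric; best_params <- params; best_epoch <- epoch
      since_improvement <- 0L
      if (!is.null(checkpoint_path))
        saveRDS(list(params = best_params, config = config, epoch = epoch),
                checkpoint_path)
    } else {
      since_improvement <- since_improvement + 1L
      if (since_improvement >= config$patience) break
    }
    if (!is.null(stop_train_acc)) {
      ## evaluate post-update training accuracy so the stopping decision
      ## reflects the parameters that will actually be returned
      post <- batch_loss_grads(params, Xtr, ytr, config, alpha_vec,
                               train = FALSE, compute_grads = FALSE)
      if (post$accuracy >= stop_train_acc) break
    }
  }
  structure(list(params = best_params, final_params = params,
                 config = config, vocab = vocab,
                 history = history, best_epoch = best_epoch,
                 alpha = alpha_vec,
                 state = list(epoch = nrow(history), step = global_step,
                              best_val_metric = best_metric,
                              epochs_since_improvement = since_improvement,
                              rng_seed = as.integer(rng_seed),
                              checkpoint_path = checkpoint_path)),
            class = "beatformer_model")
}

## init_model() seeds the RNG itself; inside train_model() the global seed
## is already set, so draw initialization from the current stream instead
init_model_with_current_rng <- function(config) {
  cnn <- init_cnn_params(config$specs, config$window_len,
                         config$cnn_out_len, config$cnn_out_dim)
  bert <- init_bert_params(config$encoder, config$cnn_out_dim)
  fus <- init_fusion_params(config$fusion)
  head <- list(W = kaiming_uniform(config$fusion$d + config$encoder$d_model,
                                   config$class_num),
               b = numeric(config$class_num))
  structure(list(cnn = cnn, bert = bert, fusion = fus, head = head),
            class = "model_params")
}

#' @export
print.beatformer_model <- function(x, ...) {
  cat(sprintf("<beatformer_model> %d classes, %d parameters\n",
              x$config$class_num, n_params(x$params)))
  cat(sprintf("  trained %d epochs (best epoch %d, val metric %.4f)\n",
              x$state$epoch, x$best_epoch, x$state$best_val_metric))
  invisible(x)
}

#' Evaluate a trained model on one split of a dataset
#'
#' @param model a `beatformer_model`.
#' @param dataset a [beat_dataset()].
#' @param split which split to evaluate (default `"test"`).
#' @return a metrics report (see [compute_metrics()]) with the confusion
#'   matrix attached as attribute `"confusion"`.
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  ds <- dataset_split(dataset, split)
  if (!nrow(ds$X)) stop_config("no beats in split '", split, "'")
  pred <- predict(model, ds)
  cm <- confusion_matrix(ds$labels, pred$labels, model$vocab)
  report <- compute_metrics(cm)
  attr(report, "confusion") <- cm
  report
}
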