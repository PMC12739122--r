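## Cross-modal alignment and gated fusion of the CNN feature sequence C and
## the transformer-encoded sequence B, plus the classification head.

#' Fusion configuration
#'
#' @param d_c CNN feature dimension.
#' @param d_b transformer feature dimension.
#' @param d shared projection dimension.
#' @param h number of cross-attention heads; `d` must be divisible by `h`
#'   (per-head dimension `d_k = d/h`). With `h = 1` the attention reduces to
#'   the single-matrix form.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(d_c, d_b, d, h = 1L) {
  if (d_c < 1 || d_b < 1 || d < 1 || h < 1) stop_config("all dims must be positive")
  if (d %% h != 0) stop_config("d must be divisible by h")
  structure(list(d_c = as.integer(d_c), d_b = as.integer(d_b),
                 d = as.integer(d), h = as.integer(h),
                 d_k = as.integer(d %/% h)),
            class = "fusion_config")
}

init_fusion_params <- function(cfg) {
  list(Wc = kaiming_uniform(cfg$d_c, cfg$d), bc = numeric(cfg$d),
       Wb = kaiming_uniform(cfg$d_b, cfg$d), bb = numeric(cfg$d),
       Wq = kaiming_uniform(cfg$d, cfg$d),
       Wk = kaiming_uniform(cfg$d, cfg$d),
       Wv = kaiming_uniform(cfg$d, cfg$d),
       Wg = kaiming_uniform(2L * cfg$d, cfg$d), bg = numeric(cfg$d))
}

#' Project both feature streams into a shared dimension
#'
#' Affine maps `C' = C Wc + bc` and `B' = B Wb + bb`.
#'
#' @param C `T` x `d_c` CNN feature sequence.
#' @param B `T` x `d_b` encoded sequence.
#' @param params fusion parameter set (fields `Wc, bc, Wb, bb`).
#' @return list with `Cp` and `Bp`, both `T` x `d`.
#' @export
project_features <- function(C, B, params) {
  if (nrow(C) != nrow(B)) stop_invalid("C and B must share their time steps")
  if (ncol(C) != nrow(params$Wc) || ncol(B) != nrow(params$Wb))
    stop_config("projection weights do not match the feature dimensions")
  list(Cp = linear_fw(C, params$Wc, params$bc)$y,
       Bp = linear_fw(B, params$Wb, params$bb)$y)
}

cross_attention_fw <- function(Cp, Bp, params, cfg, mask = NULL) {
  Qa <- Cp %*% params$Wq
  Ka <- Bp %*% params$Wk
  Va <- Bp %*% params$Wv
  dk <- cfg$d_k; h <- cfg$h
  Fcb <- matrix(0, nrow(Cp), cfg$d)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    att <- attention_fw(Qa[, cols, drop = FALSE], Ka[, cols, drop = FALSE],
                        Va[, cols, drop = FALSE], mask)
    Fcb[, cols] <- att$y
    heads[[i]] <- att$cache
  }
  list(y = Fcb, cache = list(heads = heads, Cp = Cp, Bp = Bp, h = h, dk = dk))
}

cross_attention_bw <- function(dF, cache, params) {
  h <- cache$h; dk <- cache$dk
  dQa <- matrix(0, nrow(dF), h * dk)
  dKa <- matrix(0, nrow(cache$Bp), h * dk)
  dVa <- matrix(0, nrow(cache$Bp), h * dk)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    ab <- attention_bw(dF[, cols, drop = FALSE], cache$heads[[i]])
    dQa[, cols] <- ab$dQ; dKa[, cols] <- ab$dK; dVa[, cols] <- ab$dV
  }
  list(dCp = dQa %*% t(params$Wq),
       dBp = dKa %*% t(params$Wk) + dVa %*% t(params$Wv),
       grads = list(Wq = crossprod(cache$Cp, dQa),
                    Wk = crossprod(cache$Bp, dKa),
                    Wv = crossprod(cache$Bp, dVa)))
}

#' Cross-modal attention between the two projected streams
#'
#' Queries come from the CNN stream, keys and values from the encoded
#' stream: `A = softmax((C' Wq)(B' Wk)' / sqrt(d_k))`, `F_CB = A (B' Wv)`,
#' computed per head over `h` blocks of `d/h` columns and concatenated.
#'
#' @param Cp,Bp projected streams from [project_features()], both `T` x `d`.
#' @param params fusion parameter set (`Wq, Wk, Wv`, each `d` x `d`).
#' @param config a [fusion_config()].
#' @param mask optional key-validity flags for the `Bp` rows.
#' @return `T` x `d` aligned feature sequence.
#' @export
cross_modal_attention <- function(Cp, Bp, params, config, mask = NULL) {
  cross_attention_fw(Cp, Bp, params, config, mask)$y
}

gated_fusion_fw <- function(Cp, Fcb, params) {
  cat_in <- cbind(Cp, Fcb)
  pre <- sweep(cat_in %*% params$Wg, 2L, params$bg, "+")
  G <- 1 / (1 + exp(-pre))
  list(y = G * Cp + (1 - G) * Fcb,
       cache = list(G = G, Cp = Cp, Fcb = Fcb, cat_in = cat_in))
}

gated_fusion_bw <- function(dF, cache, params) {
  G <- cache$G
  dG <- dF * (cache$Cp - cache$Fcb)
  dpre <- dG * G * (1 - G)
  dcat <- dpre %*% t(params$Wg)
  d <- ncol(G)
  list(dCp = dF * G + dcat[, seq_len(d), drop = FALSE],
       dFcb = dF * (1 - G) + dcat[, d + seq_len(d), drop = FALSE],
       grads = list(Wg = crossprod(cache$cat_in, dpre), bg = colSums(dpre)))
}

#' Gated fusion of the aligned streams
#'
#' Sigmoid gates computed from the concatenated inputs,
#' `g_t = sigmoid(Wg [C'_t ; F_CB,t] + bg)`, blend the streams elementwise:
#' `F_t = g_t * C'_t + (1 - g_t) * F_CB,t`. Every fused element therefore
#' lies between its two source elements.
#'
#' @param Cp projected CNN stream (`T` x `d`).
#' @param Fcb cross-modal attention output (`T` x `d`).
#' @param params fusion parameter set (`Wg` of shape `2d` x `d`, `bg`).
#' @return fused sequence `F` (`T` x `d`).
#' @export
gated_fusion <- function(Cp, Fcb, params) {
  if (!all(dim(Cp) == dim(Fcb))) stop_invalid("Cp and Fcb must share a shape")
  gated_fusion_fw(Cp, Fcb, params)$y
}

classify_fw <- function(Fseq, summary_vec, head, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(Fseq))
  pooled <- colMeans(Fseq[mask, , drop = FALSE])
  feat <- matrix(c(pooled, summary_vec), nrow = 1L)
  lin <- linear_fw(feat, head$W, head$b)
  z <- as.numeric(lin$y)
  p <- softmax_vec(z)
  list(probs = p, cache = list(lin = lin$cache, mask = mask,
                               Tn = nrow(Fseq), d = ncol(Fseq), z = z))
}

classify_bw <- function(dz, cache) {
  lb <- linear_bw(matrix(dz, nrow = 1L), cache$lin)
  dfeat <- as.numeric(lb$dx)
  dpooled <- dfeat[seq_len(cache$d)]
  dsummary <- dfeat[-seq_len(cache$d)]
  dF <- matrix(0, cache$Tn, cache$d)
  n_valid <- sum(cache$mask)
  dF[cache$mask, ] <- matrix(dpooled / n_valid, n_valid, cache$d, byrow = TRUE)
  list(dF = dF, dsummary = dsummary,
       grads = list(W = lb$dW, b = lb$db))
}

#' Classify a fused sequence
#'
#' Mean-pools the fused sequence over valid time steps, concatenates the
#' [CLS] summary vector, and applies a linear map followed by softmax.
#'
#' @param Fseq fused sequence (`T` x `d`).
#' @param summary [CLS] summary vector.
#' @param head_weights list with `W` (`(d + d_model)` x `class_num`) and `b`.
#' @param mask optional validity flags for the rows of `Fseq`.
#' @return class-probability vector summing to 1.
#' @export
classify_fused <- function(Fseq, summary, head_weights, mask = NULL) {
  if (ncol(head_weights$W) < 2) stop_config("at least 2 classes required")
  classify_fw(Fseq, summary, head_weights, mask)$probs
}
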