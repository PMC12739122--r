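## Shared differentiable primitives. Every *_fw returns list(y, cache);
## every *_bw consumes the upstream gradient and the cache and returns the
## input gradient plus parameter gradients. Sequences are T x d matrices.

linear_fw <- function(x, W, b) {
  y <- x %*% W
  if (!is.null(b)) y <- sweep(y, 2L, b, "+")
  list(y = y, cache = list(x = x, W = W))
}

linear_bw <- function(dy, cache) {
  list(dx = dy %*% t(cache$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_bw <- function(dy, mask) dy * mask

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  list(y = x * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}

dropout_bw <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  dy * cache$keep / (1 - cache$rate)
}

## row-wise softmax; -Inf logits become exact zeros
softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E[is.na(E)] <- 0  # rows that are all -Inf: caller must catch
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## layer normalization over the feature dimension, learned gain/bias
layernorm_fw <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * rep(1, nrow(x)) %o% g, 2L, b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bw <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  dxhat <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

## unfold a length-L, C-channel sequence into conv rows: output row t holds
## the K consecutive time steps starting at t, channel blocks side by side
## (column block k covers all channels at offset k)
im2col_valid <- function(x, K) {
  L <- nrow(x)
  L_out <- L - K + 1L
  do.call(cbind, lapply(seq_len(K), function(k) x[k:(L_out + k - 1L), , drop = FALSE]))
}

col2im_valid <- function(dcol, K, L, C) {
  dx <- matrix(0, L, C)
  L_out <- L - K + 1L
  for (k in seq_len(K)) {
    block <- dcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dx[k:(L_out + k - 1L), ] <- dx[k:(L_out + k - 1L), ] + block
  }
  dx
}

pad_rows <- function(x, before, after) {
  rbind(matrix(0, before, ncol(x)), x, matrix(0, after, ncol(x)))
}

## "same" 1-D convolution (odd K): zero-pad so output length == input length
conv_same_fw <- function(x, W, b, K) {
  pad <- (K - 1L) %/% 2L
  xp <- pad_rows(x, pad, pad)
  cols <- im2col_valid(xp, K)
  lin <- linear_fw(cols, W, b)
  list(y = lin$y, cache = list(lin = lin$cache, K = K, L = nrow(x), C = ncol(x), pad = pad))
}

conv_same_bw <- function(dy, cache) {
  lb <- linear_bw(dy, cache$lin)
  dxp <- col2im_valid(lb$dx, cache$K, cache$L + 2L * cache$pad, cache$C)
  list(dx = dxp[(cache$pad + 1L):(cache$pad + cache$L), , drop = FALSE],
       dW = lb$dW, db = lb$db)
}

## depthwise "same" convolution: one length-K kernel per channel
depthwise_same_fw <- function(x, W, b, K) {
  pad <- (K - 1L) %/% 2L
  xp <- pad_rows(x, pad, pad)
  Tn <- nrow(x); d <- ncol(x)
  y <- matrix(rep(b, each = Tn), Tn, d)
  for (k in seq_len(K))
    y <- y + xp[k:(Tn + k - 1L), , drop = FALSE] *
      matrix(W[k, ], Tn, d, byrow = TRUE)
  list(y = y, cache = list(xp = xp, K = K, Tn = Tn, d = d, pad = pad, W = W))
}

depthwise_same_bw <- function(dy, cache) {
  xp <- cache$xp; K <- cache$K; Tn <- cache$Tn; d <- cache$d
  dW <- matrix(0, K, d)
  dxp <- matrix(0, nrow(xp), d)
  for (k in seq_len(K)) {
    rows <- k:(Tn + k - 1L)
    dW[k, ] <- colSums(dy * xp[rows, , drop = FALSE])
    dxp[rows, ] <- dxp[rows, ] + dy * matrix(cache$W[k, ], Tn, d, byrow = TRUE)
  }
  list(dx = dxp[(cache$pad + 1L):(cache$pad + Tn), , drop = FALSE],
       dW = dW, db = colSums(dy))
}

## non-overlapping max pooling along time; trailing partial window kept
maxpool_fw <- function(x, window) {
  L <- nrow(x); C <- ncol(x)
  L_out <- ceiling(L / window)
  y <- matrix(0, L_out, C)
  arg <- matrix(0L, L_out, C)
  for (j in seq_len(L_out)) {
    rows <- ((j - 1L) * window + 1L):min(j * window, L)
    block <- x[rows, , drop = FALSE]
    w <- max.col(t(block), ties.method = "first")
    arg[j, ] <- rows[w]
    y[j, ] <- block[cbind(w, seq_len(C))]
  }
  list(y = y, cache = list(arg = arg, L = L, C = C))
}

maxpool_bw <- function(dy, cache) {
  dx <- matrix(0, cache$L, cache$C)
  for (c_i in seq_len(cache$C))
    dx[cache$arg[, c_i], c_i] <- dy[, c_i]
  dx
}

## scaled dot-product attention for one head; mask flags valid KEYS
attention_fw <- function(Qm, Km, Vm, mask = NULL) {
  dk <- ncol(Km)
  S <- tcrossprod(Qm, Km) / sqrt(dk)
  if (!is.null(mask)) S[, !mask] <- -Inf
  A <- softmax_rows(S)
  list(y = A %*% Vm, cache = list(A = A, Qm = Qm, Km = Km, Vm = Vm, dk = dk))
}

attention_bw <- function(dy, cache) {
  A <- cache$A
  dA <- tcrossprod(dy, cache$Vm)
  dVm <- crossprod(A, dy)
  dS <- A * (dA - rowSums(dA * A))  # masked cols: A == 0 -> dS == 0
  scale <- 1 / sqrt(cache$dk)
  list(dQ = (dS %*% cache$Km) * scale,
       dK = (crossprod(dS, cache$Qm)) * scale,
       dV = dVm)
}

## recursive helpers over nested parameter lists --------------------------

## apply f leaf-wise to one or more congruent nested lists of numerics
map_params <- function(f, p, ...) {
  others <- list(...)
  if (is.numeric(p)) return(do.call(f, c(list(p), others)))
  out <- vector("list", length(p))
  names(out) <- names(p)
  for (i in seq_along(p)) {
    if (is.null(p[[i]])) { out[i] <- list(NULL); next }
    out[[i]] <- do.call(map_params,
                        c(list(f, p[[i]]), lapply(others, `[[`, i)))
  }
  out
}

zeros_like <- function(p) map_params(function(x) x * 0, p)

add_params <- function(a, b) map_params(function(x, y) x + y, a, b)

scale_params <- function(p, s) map_params(function(x) x * s, p)

flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, function(q) if (is.null(q)) numeric(0) else flatten_params(q)),
         use.names = FALSE)
}

n_params <- function(p) length(flatten_params(p))
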