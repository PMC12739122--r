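## Local morphological feature extraction: stacked valid 1-D convolutions,
## ReLU, non-overlapping max pooling, residual 1x1 channel matching, dropout,
## and a fully connected projection to a fixed-length feature sequence.

#' Specify one convolution block
#'
#' A block applies a valid (un-padded) 1-D convolution, adds a residual copy
#' of its input (passed through a 1x1 convolution if and only if the channel
#' counts differ, and center-cropped to the valid length), applies ReLU,
#' max-pools with a non-overlapping window, and applies dropout.
#'
#' @param in_channels,out_channels channel counts (>= 1).
#' @param kernel_size odd kernel width (default 3).
#' @param pool_window pooling window (default 2).
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @return object of class `conv_spec`.
#' @export
conv_spec <- function(in_channels, out_channels, kernel_size = 3L,
                      pool_window = 2L, dropout_rate = 0.3) {
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop_invalid("kernel_size must be odd and >= 1")
  if (pool_window < 1) stop_invalid("pool_window must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate must lie in [0, 1)")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_window = as.integer(pool_window),
                 dropout_rate = dropout_rate),
            class = "conv_spec")
}

#' Valid 1-D convolution of a signal with a kernel
#'
#' Computes `y_t = sum_k w_k * x_{t-k+1} + bias` for every position `t` where
#' the full kernel window lies inside the signal, i.e. output length
#' `length(x) - K + 1`.
#'
#' @param x numeric input vector.
#' @param kernel numeric kernel of length `K <= length(x)`.
#' @param bias scalar added to every output (default 0).
#' @return numeric vector of length `length(x) - K + 1`.
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, 1, 1))  # 6 9
#' @export
conv1d <- function(x, kernel, bias = 0) {
  if (length(kernel) == 0) stop_invalid("kernel must be non-empty")
  K <- length(kernel)
  if (length(x) < K) stop_invalid("signal shorter than kernel")
  ## y_t = sum_k w_k x_{t-k+1}: correlate with the index-reversed kernel
  cols <- im2col_valid(matrix(x, ncol = 1L), K)
  as.numeric(cols %*% rev(kernel) + bias)
}

#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`.
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' Non-overlapping max pooling of a vector
#'
#' Splits `x` into consecutive windows of the given size (the trailing
#' window may be shorter) and takes the maximum of each, so the output has
#' length `ceiling(length(x) / window)`.
#'
#' @param x numeric vector.
#' @param window pooling window size (>= 1).
#' @return pooled numeric vector.
#' @export
maxpool <- function(x, window) {
  if (length(x) == 0) stop_invalid("input must be non-empty")
  if (window < 1) stop_invalid("window must be >= 1")
  as.numeric(maxpool_fw(matrix(x, ncol = 1L), as.integer(window))$y)
}

## length after a stack of conv blocks applied to a window of w samples
cnn_output_length <- function(window_len, specs) {
  L <- window_len
  for (sp in specs) {
    L <- L - sp$kernel_size + 1L
    L <- ceiling(L / sp$pool_window)
  }
  as.integer(L)
}

## Kaiming-uniform init, fan_in from the weight's first dimension
kaiming_uniform <- function(nrow_, ncol_) {
  lim <- sqrt(6 / nrow_)
  matrix(stats::runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

## initialize all parameters of the CNN front end
init_cnn_params <- function(specs, window_len, out_len, out_dim) {
  conv <- lapply(specs, function(sp) {
    W <- kaiming_uniform(sp$kernel_size * sp$in_channels, sp$out_channels)
    Wres <- if (sp$in_channels != sp$out_channels)
      kaiming_uniform(sp$in_channels, sp$out_channels) else NULL
    list(W = W, b = numeric(sp$out_channels), Wres = Wres)
  })
  L_fin <- cnn_output_length(window_len, specs)
  C_fin <- specs[[length(specs)]]$out_channels
  list(conv = conv,
       fc = list(W = kaiming_uniform(L_fin * C_fin, out_len * out_dim),
                 b = numeric(out_len * out_dim)))
}

## one block: valid conv -> + residual (1x1 iff channels differ, center
## cropped) -> ReLU -> maxpool -> dropout
cnn_block_fw <- function(x, sp, pw, train) {
  K <- sp$kernel_size
  cols <- im2col_valid(x, K)
  lin <- linear_fw(cols, pw$W, pw$b)
  crop <- ((K - 1L) %/% 2L + 1L):(nrow(x) - (K - 1L) %/% 2L)
  xc <- x[crop, , drop = FALSE]
  if (is.null(pw$Wres)) {
    res <- xc; res_cache <- NULL
  } else {
    rl <- linear_fw(xc, pw$Wres, NULL)
    res <- rl$y; res_cache <- rl$cache
  }
  act <- relu_fw(lin$y + res)
  pool <- maxpool_fw(act$y, sp$pool_window)
  drop <- dropout_fw(pool$y, sp$dropout_rate, train)
  list(y = drop$y,
       cache = list(lin = lin$cache, res_cache = res_cache, crop = crop,
                    act = act$cache, pool = pool$cache, drop = drop$cache,
                    K = K, L = nrow(x), C = ncol(x), has_res = !is.null(pw$Wres)))
}

cnn_block_bw <- function(dy, cache) {
  d_pool <- dropout_bw(dy, cache$drop)
  d_act <- maxpool_bw(d_pool, cache$pool)
  d_pre <- relu_bw(d_act, cache$act)
  lb <- linear_bw(d_pre, cache$lin)
  dx <- col2im_valid(lb$dx, cache$K, cache$L, cache$C)
  if (cache$has_res) {
    rb <- linear_bw(d_pre, cache$res_cache)
    dx[cache$crop, ] <- dx[cache$crop, ] + rb$dx
    dWres <- rb$dW
  } else {
    dx[cache$crop, ] <- dx[cache$crop, ] + d_pre
    dWres <- NULL
  }
  list(dx = dx, grads = list(W = lb$dW, b = lb$db, Wres = dWres))
}

cnn_fw_one <- function(beat, specs, params, out_len, out_dim, train) {
  x <- matrix(beat, ncol = 1L)
  caches <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    blk <- cnn_block_fw(x, specs[[i]], params$conv[[i]], train)
    x <- blk$y
    caches[[i]] <- blk$cache
  }
  flat <- matrix(as.numeric(x), nrow = 1L)
  fc <- linear_fw(flat, params$fc$W, params$fc$b)
  C_seq <- matrix(as.numeric(fc$y), nrow = out_len, ncol = out_dim)
  list(C = C_seq,
       cache = list(blocks = caches, fc = fc$cache,
                    fin_dim = dim(x), out_len = out_len, out_dim = out_dim))
}

cnn_bw_one <- function(dC, cache, specs) {
  dflat <- matrix(as.numeric(dC), nrow = 1L)
  fb <- linear_bw(dflat, cache$fc)
  dx <- matrix(as.numeric(fb$dx), cache$fin_dim[1L], cache$fin_dim[2L])
  grads_conv <- vector("list", length(specs))
  for (i in rev(seq_along(specs))) {
    bb <- cnn_block_bw(dx, cache$blocks[[i]])
    dx <- bb$dx
    grads_conv[[i]] <- bb$grads
  }
  list(grads = list(conv = grads_conv, fc = list(W = fb$dW, b = fb$db)))
}

#' Run the CNN front end over a batch of beats
#'
#' Applies each convolution block (valid conv, residual with 1x1 channel
#' matching, ReLU, max pooling, dropout) and the fully connected projection,
#' producing one fixed-size feature sequence (`out_len` x `out_dim`) per
#' beat. Dropout is active only when `train_mode = TRUE`; with it off the
#' output is deterministic.
#'
#' @param beats numeric matrix, one beat per row (shared window length).
#' @param specs list of [conv_spec()]s; each block's `in_channels` must match
#'   the previous block's `out_channels` (1 for the first).
#' @param out_len,out_dim shape of the output feature sequence.
#' @param weights parameter set from [init_cnn_params] shaped per `specs`;
#'   if `NULL`, fresh parameters are initialized from the current RNG state.
#' @param train_mode enable dropout.
#' @return list of per-beat feature sequences (`out_len` x `out_dim`
#'   matrices), each with an all-valid `mask` attribute.
#' @export
cnn_forward <- function(beats, specs, out_len, out_dim, weights = NULL,
                        train_mode = FALSE) {
  if (is.vector(beats)) beats <- matrix(beats, nrow = 1L)
  for (i in seq_along(specs)) {
    expected <- if (i == 1L) 1L else specs[[i - 1L]]$out_channels
    if (specs[[i]]$in_channels != expected)
      stop_config("conv block ", i, " expects in_channels = ", expected)
  }
  if (is.null(weights))
    weights <- init_cnn_params(specs, ncol(beats), out_len, out_dim)
  L_fin <- cnn_output_length(ncol(beats), specs)
  C_fin <- specs[[length(specs)]]$out_channels
  if (nrow(weights$fc$W) != L_fin * C_fin)
    stop_config("fc weights do not match the conv stack output size")
  lapply(seq_len(nrow(beats)), function(i) {
    out <- cnn_fw_one(beats[i, ], specs, weights, out_len, out_dim, train_mode)$C
    attr(out, "mask") <- rep(TRUE, out_len)
    out
  })
}
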