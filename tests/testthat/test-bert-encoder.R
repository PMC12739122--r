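test_that("scaled dot-product attention matches its closed-form cases", {
  ## one query, one unmasked key: output is that key's value row
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(2 * 4), 2); V <- matrix(rnorm(2 * 3), 2)
  out <- scaled_dot_attention(Q, K, V, mask = c(TRUE, FALSE))
  expect_equal(as.numeric(out), V[1, ], tolerance = 1e-12)
  ## identical keys: uniform weights, output = column mean of V
  K_same <- matrix(rep(rnorm(4), each = 3), 3)
  V3 <- matrix(rnorm(3 * 2), 3)
  out2 <- scaled_dot_attention(matrix(rnorm(4), 1), K_same, V3)
  expect_equal(as.numeric(out2), colMeans(V3), tolerance = 1e-9)
  expect_error(scaled_dot_attention(Q, K, V, mask = c(FALSE, FALSE)),
               "masked")
})

test_that("attention equals the brute-force oracle on random instances", {
  set.seed(202)
  for (rep_i in 1:100) {
    nq <- sample(1:5, 1); nk <- sample(1:6, 1)
    dk <- sample(1:5, 1); dv <- sample(1:4, 1)
    Q <- matrix(rnorm(nq * dk), nq); K <- matrix(rnorm(nk * dk), nk)
    V <- matrix(rnorm(nk * dv), nk)
    mask <- if (runif(1) < 0.5) NULL else {
      m <- runif(nk) < 0.7; if (!any(m)) m[1] <- TRUE; m
    }
    expect_equal(scaled_dot_attention(Q, K, V, mask),
                 oracle_attention(Q, K, V, mask), tolerance = 1e-6)
  }
})

test_that("attention rows sum to one over unmasked keys", {
  set.seed(303)
  for (rep_i in 1:25) {
    nk <- sample(2:8, 1)
    Q <- matrix(rnorm(3 * 4), 3); K <- matrix(rnorm(nk * 4), nk)
    mask <- runif(nk) < 0.6; if (!any(mask)) mask[1] <- TRUE
    att <- beatformer:::attention_fw(Q, K, matrix(rnorm(nk * 2), nk), mask)
    A <- att$cache$A
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
    expect_true(all(A[, !mask] < 1e-6))
  }
})

test_that("positional encodings are per-position distinct and additive", {
  set.seed(9)
  tab <- positional_encoding(10, 8)
  expect_equal(dim(tab), c(10L, 8L))
  dists <- as.matrix(dist(tab))
  expect_true(all(dists[upper.tri(dists)] > 0))
  x <- matrix(rnorm(10 * 8), 10)
  expect_equal((x + tab) - tab, x, tolerance = 1e-12)
})

test_that("multi-head attention keeps shape and reduces to one head", {
  cfg <- encoder_config(n_layers = 1, n_heads = 1, d_model = 4, d_k = 4,
                        d_v = 4, d_inner = 8, dropout_rate = 0, max_len = 16)
  x <- matrix(rnorm(5 * 4), 5)
  ## identity projections: multi-head == bare scaled_dot_attention
  w <- list(Wq = diag(4), bq = rep(0, 4), Wk = diag(4), bk = rep(0, 4),
            Wv = diag(4), bv = rep(0, 4), Wo = diag(4), bo = rep(0, 4))
  expect_equal(multi_head_attention(x, cfg, w),
               scaled_dot_attention(x, x, x), tolerance = 1e-9)
  cfg2 <- encoder_config(n_heads = 2, d_model = 6, d_k = 3, d_v = 3,
                         dropout_rate = 0, max_len = 16)
  set.seed(4)
  x2 <- matrix(rnorm(7 * 6), 7)
  expect_equal(dim(multi_head_attention(x2, cfg2)), c(7L, 6L))
})

test_that("masked keys receive no attention weight in any head", {
  cfg <- encoder_config(n_heads = 2, d_model = 6, d_k = 3, d_v = 3,
                        dropout_rate = 0, max_len = 16)
  set.seed(5)
  x <- matrix(rnorm(6 * 6), 6)
  w <- beatformer:::init_mha_params(cfg)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  fw <- beatformer:::mha_fw(x, w, cfg, mask)
  total_masked <- sum(vapply(fw$cache$heads,
                             function(h) sum(h$A[, !mask]), numeric(1)))
  expect_lt(total_masked, 1e-6)
})

test_that("encoder layer is the identity when sublayer outputs are zeroed", {
  cfg <- encoder_config(n_layers = 1, n_heads = 2, d_model = 6, d_k = 3,
                        d_v = 3, d_inner = 8, dropout_rate = 0, max_len = 16)
  set.seed(6)
  w <- beatformer:::init_encoder_layer_params(cfg)
  w$mha$Wo <- w$mha$Wo * 0; w$mha$bo <- w$mha$bo * 0
  w$ffn$W2 <- w$ffn$W2 * 0; w$ffn$b2 <- w$ffn$b2 * 0
  x <- matrix(rnorm(5 * 6), 5)
  expect_equal(encoder_layer(x, cfg, w), x, tolerance = 1e-12)
})

test_that("encoder layer is deterministic in eval mode and bounded at scale", {
  cfg <- encoder_config(n_layers = 1, n_heads = 2, d_model = 6, d_k = 3,
                        d_v = 3, d_inner = 8, dropout_rate = 0.5, max_len = 16)
  set.seed(7)
  w <- beatformer:::init_encoder_layer_params(cfg)
  x <- matrix(rnorm(5 * 6), 5)
  expect_identical(encoder_layer(x, cfg, w, train_mode = FALSE),
                   encoder_layer(x, cfg, w, train_mode = FALSE))
  big <- encoder_layer(x * 100, cfg, w)
  expect_true(all(is.finite(big)))
})

test_that("the [CLS] summary ignores appended masked padding", {
  cfg <- encoder_config(n_layers = 2, n_heads = 2, d_model = 8, d_k = 4,
                        d_v = 4, d_inner = 16, dropout_rate = 0, max_len = 32)
  set.seed(8)
  feats <- matrix(rnorm(6 * 5), 6, 5)
  w <- beatformer:::init_bert_params(cfg, 5L)
  base <- bert_forward(feats, cfg, w)
  padded <- rbind(feats, matrix(0, 5, 5))
  attr(padded, "mask") <- c(rep(TRUE, 6), rep(FALSE, 5))
  with_pad <- bert_forward(padded, cfg, w)
  expect_lt(max(abs(base$summary - with_pad$summary)), 1e-5)
  expect_equal(length(base$summary), 8L)
  ## masked positions carry zero output in the encoded body
  expect_true(all(with_pad$encoded[7:11, ] == 0))
})

test_that("bert_forward is deterministic in eval mode and checks max_len", {
  cfg <- encoder_config(n_layers = 1, n_heads = 2, d_model = 8, d_k = 4,
                        d_v = 4, d_inner = 16, dropout_rate = 0.3, max_len = 8)
  set.seed(9)
  feats <- matrix(rnorm(5 * 4), 5, 4)
  w <- beatformer:::init_bert_params(cfg, 4L)
  expect_identical(bert_forward(feats, cfg, w), bert_forward(feats, cfg, w))
  too_long <- matrix(rnorm(9 * 4), 9, 4)
  expect_error(bert_forward(too_long, cfg, w), "max_len")
})

test_that("every parameter receives gradient on a nonzero-loss batch", {
  cfg <- tiny_config()
  set.seed(31)
  params <- unclass(init_model(cfg, 31))
  X <- matrix(rnorm(3 * 40), 3, 40)
  res <- beatformer:::batch_loss_grads(params, X, c(1L, 2L, 3L), cfg,
                                       alpha_vec = 1, train = FALSE)
  leaves_ok <- beatformer:::map_params(function(g) any(g != 0), res$grads)
  flat <- unlist(leaves_ok)
  expect_true(all(flat), info = paste(names(flat)[!flat], collapse = ", "))
})
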