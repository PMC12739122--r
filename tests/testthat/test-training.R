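test_that("focal loss matches its closed forms", {
  expect_equal(focal_loss(c(1, 0), 1, focal_loss_spec(gamma = 3)), 0)
  expect_equal(focal_loss(c(0.5, 0.5), 1, focal_loss_spec(gamma = 0)),
               -log(0.5), tolerance = 1e-12)
  ## gamma = 2, alpha = 0.25, p_t = 0.9: 0.25 * 0.01 * (-log 0.9)
  got <- focal_loss(c(0.9, 0.1), 1, focal_loss_spec(gamma = 2, alpha = c(0.25, 0.25)))
  expect_equal(got, 0.25 * 0.01 * -log(0.9), tolerance = 1e-12)
  expect_equal(got, 2.6341e-4, tolerance = 1e-4)
  expect_error(focal_loss(c(0.9, 0.3), 1), "simplex")
  expect_warning(focal_loss(c(0, 1), 1, focal_loss_spec()), "clamped")
})

test_that("focal loss with gamma 0 and unit alpha is cross-entropy", {
  set.seed(21)
  spec <- focal_loss_spec(gamma = 0, alpha = "uniform")
  for (rep_i in 1:1000) {
    k <- sample(2:6, 1)
    p <- as.numeric(stats::rgamma(k, 1)); p <- p / sum(p)
    cl <- sample(k, 1)
    expect_equal(focal_loss(p, cl, spec), -log(p[cl]), tolerance = 1e-12)
  }
})

test_that("focal loss decreases as the true-class probability grows", {
  spec <- focal_loss_spec(gamma = 2, alpha = c(0.5, 0.5))
  grid <- seq(0.01, 0.99, by = 0.01)
  losses <- vapply(grid, function(p) focal_loss(c(p, 1 - p), 1, spec), 0)
  expect_true(all(diff(losses) < 0))
})

test_that("the focal-loss logit gradient matches finite differences", {
  set.seed(22)
  for (gamma in c(0, 0.5, 2)) {
    z <- rnorm(4); alpha <- c(0.3, 1, 2, 0.8)
    probs <- exp(z - max(z)); probs <- probs / sum(probs)
    fl <- beatformer:::focal_loss_grad(probs, 2L, gamma, alpha)
    num <- vapply(1:4, function(j) {
      h <- 1e-6
      zp <- z; zp[j] <- zp[j] + h; zm <- z; zm[j] <- zm[j] - h
      pp <- exp(zp - max(zp)); pp <- pp / sum(pp)
      pm <- exp(zm - max(zm)); pm <- pm / sum(pm)
      (beatformer:::focal_loss_grad(pp, 2L, gamma, alpha)$loss -
         beatformer:::focal_loss_grad(pm, 2L, gamma, alpha)$loss) / (2 * h)
    }, 0)
    expect_equal(fl$dz, num, tolerance = 1e-5)
  }
})

test_that("the LR schedule warms up linearly then decays as 1/sqrt(step)", {
  spec <- schedule_spec(lr_max = 0.002, warmup_steps = 100, total_steps = 1000)
  expect_equal(lr_at_step(100, spec), 0.002)
  expect_equal(lr_at_step(50, spec), 0.001)
  expect_equal(lr_at_step(400, spec), 0.001)
  ## monotone up to warm-up, monotone down after
  lrs <- lr_at_step(1:1000, spec)
  expect_true(all(diff(lrs[1:100]) >= 0))
  expect_true(all(diff(lrs[100:1000]) <= 0))
  expect_error(lr_at_step(0, spec), "1-based")
  expect_error(schedule_spec(1e-3, 0, 10), "warmup")
})

test_that("analytic model gradients match central finite differences", {
  cfg <- tiny_config()
  set.seed(24)
  params <- unclass(init_model(cfg, 24))
  X <- matrix(rnorm(2 * 40), 2, 40); y <- c(1L, 3L)
  alpha <- c(0.5, 1.2, 2.0)
  loss_of <- function(p) beatformer:::batch_loss_grads(
    p, X, y, cfg, alpha, train = FALSE, compute_grads = FALSE)$loss
  res <- beatformer:::batch_loss_grads(params, X, y, cfg, alpha, train = FALSE)
  ## probe a handful of coordinates in every stage of the network
  probes <- list(list("cnn", "conv", 1L, "W"), list("cnn", "conv", 2L, "Wres"),
                 list("cnn", "fc", "W"), list("bert", "emb", "W"),
                 list("bert", "layers", 1L, "mha", "Wq"),
                 list("bert", "layers", 1L, "ffn", "W1"),
                 list("bert", "layers", 1L, "ln1", "g"),
                 list("bert", "cls"), list("bert", "trail", "W"),
                 list("fusion", "Wq"), list("fusion", "Wg"), list("head", "W"))
  h <- 1e-5
  for (path in probes) {
    leaf <- params; g <- res$grads
    for (k in path) { leaf <- leaf[[k]]; g <- g[[k]] }
    for (j in sample(length(leaf), min(3L, length(leaf)))) {
      bump <- function(delta) {
        set_leaf <- function(pl, pth) {
          if (length(pth) == 0L) { pl[j] <- pl[j] + delta; return(pl) }
          pl[[pth[[1L]]]] <- set_leaf(pl[[pth[[1L]]]], pth[-1L])
          pl
        }
        set_leaf(params, path)
      }
      num <- (loss_of(bump(h)) - loss_of(bump(-h))) / (2 * h)
      expect_equal(g[j], num, tolerance = 1e-4,
                   label = paste(c(path, j), collapse = "/"))
    }
  }
})

test_that("one Adam step at small lr decreases the batch loss", {
  cfg <- tiny_config()
  set.seed(23)
  params <- unclass(init_model(cfg, 23))
  X <- matrix(rnorm(4 * 40), 4, 40); y <- c(1L, 2L, 3L, 1L)
  res <- beatformer:::batch_loss_grads(params, X, y, cfg, 1, train = FALSE)
  st <- beatformer:::adam_init(params)
  upd <- beatformer:::adam_step(params, res$grads, st, lr = 1e-4)
  after <- beatformer:::batch_loss_grads(upd$params, X, y, cfg, 1,
                                         train = FALSE, compute_grads = FALSE)
  expect_lt(after$loss, res$loss)
})

test_that("training is reproducible: same seed, identical histories", {
  ds <- tiny_dataset(n_per_class = 10)
  ds <- split_dataset(ds, c(0.6, 0.2, 0.2), rng_seed = 1)
  cfg <- tiny_config(vocab = c("A", "B"), max_epochs = 2L,
                     conv_dropout = 0.2, encoder_dropout = 0.2, batch_size = 4L)
  m1 <- train_model(ds, cfg, rng_seed = 7)
  m2 <- train_model(ds, cfg, rng_seed = 7)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(beatformer:::flatten_params(m1$params),
                   beatformer:::flatten_params(m2$params))
})

test_that("early stopping halts exactly at patience exhaustion", {
  ds <- tiny_dataset(n_per_class = 8)
  ds <- split_dataset(ds, c(0.6, 0.2, 0.2), rng_seed = 2)
  cfg <- tiny_config(vocab = c("A", "B"), max_epochs = 50L, patience = 2L,
                     batch_size = 4L)
  ck <- tempfile(fileext = ".rds")
  ## rigged selection metric that strictly worsens from epoch 1
  m <- train_model(ds, cfg, rng_seed = 3, checkpoint_path = ck,
                   val_metric_fn = function(epoch, report) -epoch)
  expect_equal(nrow(m$history), 3L)  # epoch 1 best, epochs 2-3 exhaust patience
  expect_equal(m$best_epoch, 1L)
  expect_equal(m$state$epochs_since_improvement, 2L)
  saved <- readRDS(ck)
  expect_equal(saved$epoch, 1L)
})

test_that("a tiny model memorizes a tiny beat set perfectly", {
  ds <- tiny_dataset(n_per_class = 16, noise_sd = 0.02)
  ## use most beats for train, a token val split
  set.seed(1)
  ds$split <- sample(rep(c("train", "val"), times = c(28, 4)))
  cfg <- tiny_config(vocab = c("A", "B"), max_epochs = 60L, patience = 60L,
                     batch_size = 8L, lr_max = 3e-3)
  ds <- normalize_beats(ds)
  m <- train_model(ds, cfg, rng_seed = 5, stop_train_acc = 1.0)
  tr <- dataset_split(ds, "train")
  final <- structure(list(params = m$final_params, config = cfg,
                          vocab = cfg$vocab), class = "beatformer_model")
  expect_equal(mean(predict(final, tr)$labels == tr$labels), 1.0)
  expect_lte(nrow(m$history), 60L)
})

test_that("two-stage mode leaves the frozen encoders untouched", {
  ds <- tiny_dataset(n_per_class = 8)
  ds <- split_dataset(ds, c(0.6, 0.2, 0.2), rng_seed = 4)
  cfg <- tiny_config(vocab = c("A", "B"), max_epochs = 2L, batch_size = 4L,
                     two_stage = TRUE)
  m <- train_model(ds, cfg, rng_seed = 9)
  set.seed(9)
  init <- beatformer:::init_model_with_current_rng(cfg)
  expect_identical(beatformer:::flatten_params(m$params$cnn),
                   beatformer:::flatten_params(init$cnn))
  expect_identical(beatformer:::flatten_params(m$params$bert),
                   beatformer:::flatten_params(init$bert))
  expect_false(identical(beatformer:::flatten_params(m$params$head),
                         beatformer:::flatten_params(init$head)))
})
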