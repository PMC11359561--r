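test_that("conv block equals the four-nested-loop oracle", {
  set.seed(50)
  for (rep in 1:30) {
    D <- sample(4:8, 1); M <- sample(2:5, 1)
    p <- sample(1:3, 1); q <- sample(seq_len(M), 1)
    C <- sample(1:3, 1)
    X <- matrix(rnorm(D * M), D, M)
    w <- array(rnorm(p * q * C), dim = c(p, q, C))
    b <- rnorm(C)
    expect_equal(conv_block(X, w, b, activation = "relu"),
                 oracle_conv(X, w, b, relu = TRUE))
    expect_equal(conv_block(X, w, b, activation = "identity"),
                 oracle_conv(X, w, b, relu = FALSE))
  }
})

test_that("conv block special cases: identity kernel, zero input", {
  set.seed(51)
  X <- matrix(runif(24, -2, 2), 6, 4)
  # 1x1 unit kernel + identity activation reduces to per-timestep max
  out <- conv_block(X, matrix(1, 1, 1), 0, activation = "identity")
  expect_equal(out[, 1], apply(X, 1, max))
  expect_true(all(conv_block(matrix(0, 5, 3),
                             array(rnorm(4), c(2, 2, 1)), 0) == 0))
  expect_error(conv_block(matrix(c(1, NA, 1, 1), 2, 2),
                          matrix(1, 1, 1), 0), "non-finite")
})

test_that("attention: single position, row-stochastic, dominant key", {
  Q <- matrix(rnorm(4), 1, 4)
  V <- matrix(c(7, 8, 9), 1, 3)
  res <- attention(Q, Q, V)
  expect_equal(res$weights, matrix(1, 1, 1))
  expect_equal(res$output, V)

  set.seed(52)
  Q2 <- matrix(rnorm(40), 10, 4); K2 <- matrix(rnorm(40), 10, 4)
  V2 <- matrix(rnorm(30), 10, 3)
  res2 <- attention(Q2, K2, V2)
  expect_equal(rowSums(res2$weights), rep(1, 10))
  expect_true(all(res2$weights >= 0))

  # orthogonal keys, one huge dot product: output collapses to matched row
  K3 <- diag(4) * 100
  Q3 <- matrix(c(100, 0, 0, 0), 1, 4)
  V3 <- matrix(1:8, 4, 2)
  res3 <- attention(Q3, K3, V3)
  expect_equal(drop(res3$output), as.numeric(V3[1, ]), tolerance = 1e-6)
})

test_that("forward pass: shape, determinism, zero-weight head", {
  cfg <- tiny_model_cfg()
  m1 <- build_convformer(cfg, 3L)
  m2 <- build_convformer(cfg, 3L)
  set.seed(53)
  X <- matrix(runif(36), 12, 3)
  y1 <- forward_convformer(m1, X)
  expect_length(y1, 4L)
  expect_identical(y1, forward_convformer(m2, X))   # same seed, same weights
  m1$params$Wout[] <- 0
  m1$params$bout <- c(1, 2, 3, 4)
  expect_equal(forward_convformer(m1, X), c(1, 2, 3, 4))
  expect_error(forward_convformer(m1, matrix(1, 5, 3)), "shape")
})

test_that("analytic gradients match central finite differences", {
  cfg <- convformer_config(window_d = 6L, horizon_tau = 3L,
                           conv_kernel = c(2L, 2L), conv_channels = 3L,
                           d_model = 8L, n_heads = 2L, n_layers = 2L,
                           d_ff = 10L, seed = 7L)
  m <- build_convformer(cfg, 4L)
  set.seed(54)
  X <- matrix(rnorm(24), 6, 4)
  y <- rnorm(3)
  fw <- convformer:::cf_forward(m, X, keep_cache = TRUE)
  g <- convformer:::cf_backward(m, fw$cache, 2 * (fw$y - y) / 3)
  eps <- 1e-6
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in idx) {
      m2 <- m
      m2$params[[nm]][i] <- m$params[[nm]][i] + eps
      lp <- mean((convformer:::cf_forward(m2, X)$y - y)^2)
      m2$params[[nm]][i] <- m$params[[nm]][i] - eps
      lm_ <- mean((convformer:::cf_forward(m2, X)$y - y)^2)
      num <- (lp - lm_) / (2 * eps)
      ana <- g[[nm]][i]
      # key-projection bias gradients are analytically zero (a constant
      # shift of all keys leaves row softmax unchanged): floor the scale
      expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("training overfits a noiseless deterministic target to < 1e-3", {
  T_ <- 220L
  vals <- cbind(PM2.5 = 10 + 0.1 * seq_len(T_) +
                  5 * sin(2 * pi * seq_len(T_) / 24),
                X = 20 + 10 * cos(2 * pi * seq_len(T_) / 24))
  wd <- split_and_window(make_panel(vals), D = 24, tau = 4)
  cfg <- convformer_config(window_d = 24L, horizon_tau = 4L,
                           conv_kernel = c(3L, 2L), conv_channels = 4L,
                           d_model = 16L, n_heads = 2L, n_layers = 1L,
                           d_ff = 24L, batch_size = 16L, max_epochs = 40L,
                           patience = 40L, learning_rate = 5e-3, seed = 6L)
  m <- build_convformer(cfg, ncol(wd$values))
  m <- train_convformer(m, wd)
  expect_lt(min(m$history$train_loss), 1e-3)
})

test_that("early stopping honours patience and restores best weights", {
  wd <- sine_windowed(T_ = 150L, D = 12L, tau = 4L, seed = 3L)
  cfg <- tiny_model_cfg(max_epochs = 15L, patience = 0L,
                        learning_rate = 0.3)  # large rate to force bouncing
  m <- train_convformer(build_convformer(cfg, ncol(wd$values)), wd)
  h <- m$history
  # with patience 0, training stops exactly one epoch past the first
  # non-improvement of the running-best validation loss
  running_best <- cummin(h$val_loss)
  first_bad <- which(h$val_loss >= c(Inf, running_best[-nrow(h)]))[1]
  if (!is.na(first_bad)) expect_equal(nrow(h), first_bad)
  expect_equal(m$best_epoch, which.min(h$val_loss))
})

test_that("training is deterministic across repeated runs", {
  wd <- sine_windowed(T_ = 120L, D = 12L, tau = 4L, seed = 4L)
  cfg <- tiny_model_cfg(max_epochs = 2L)
  m1 <- train_convformer(build_convformer(cfg, ncol(wd$values)), wd)
  m2 <- train_convformer(build_convformer(cfg, ncol(wd$values)), wd)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("prediction: shapes, residual convention, cross-module RMSE", {
  wd <- sine_windowed(T_ = 150L, D = 12L, tau = 4L, seed = 5L)
  cfg <- tiny_model_cfg(max_epochs = 2L)
  m <- train_convformer(build_convformer(cfg, ncol(wd$values)), wd)
  fc <- predict_convformer(m, wd, split = "test")
  n_test <- sum(wd$index$split == "test")
  expect_equal(dim(fc$point_predictions), c(n_test, 4L))
  expect_equal(fc$residuals, fc$actuals - fc$point_predictions)
  expect_equal(rmse(as.vector(fc$actuals), as.vector(fc$point_predictions)),
               sqrt(mean(fc$residuals^2)))
  # actuals are in original units (straight from the unscaled panel)
  expect_true(all(fc$actuals >= 9 & fc$actuals <= 31))
})

test_that("checkpoint JSON round trip preserves the model exactly", {
  wd <- sine_windowed(T_ = 120L, D = 12L, tau = 4L, seed = 6L)
  cfg <- tiny_model_cfg(max_epochs = 1L)
  m <- train_convformer(build_convformer(cfg, ncol(wd$values)), wd)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  X <- matrix(runif(12 * ncol(wd$values)), 12)
  expect_equal(forward_convformer(m2, X), forward_convformer(m, X))
})

test_that("config invariants are enforced", {
  expect_error(convformer_config(d_model = 10, n_heads = 4), "divide")
  expect_error(convformer_config(window_d = 4, conv_kernel = c(5, 1)),
               "kernel")
  expect_error(build_convformer(tiny_model_cfg(), 1L), "n_features")
  expect_error(convformer_config(dropout = 1.5), "dropout")
})
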