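# The ConvFormer point forecaster: a convolution + max-pooling block over
# the D x M input window, a sinusoidal positional encoding, an encoder-only
# stack of multi-head self-attention + feed-forward sublayers (residual +
# layer normalization), and a single linear head emitting all tau horizon
# steps at once (direct multi-output; nothing is fed back recursively).
# Implemented in plain R with hand-written backpropagation and Adam;
# deliberately small so that desk-scale CPU training stays in minutes.

#' ConvFormer model configuration
#'
#' The published architecture leaves all sizes unreported; these defaults
#' are deliberately small for CPU training and every one can be overridden.
#' `conv_channels` sets the number of convolution feature maps whose
#' max-pooled (over the feature axis) outputs form the sequence fed to the
#' attention stack; `strict_pool = TRUE` instead collapses to a single
#' pooled channel (the literal `D x 1` reading) for comparison.
#'
#' @param window_d input window length D (hours).
#' @param horizon_tau forecast horizon tau (hours), all emitted at once.
#' @param conv_kernel integer `c(p, q)` kernel size (time x feature).
#' @param conv_channels number of convolution channels.
#' @param d_model attention width; must be divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @param n_layers number of encoder layers.
#' @param d_ff feed-forward width, default `2 * d_model`.
#' @param dropout dropout rate on sublayer outputs (default 0; at desk
#'   scale regularization comes from early stopping).
#' @param loss only `"mse"` is implemented.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience: training stops once validation
#'   loss has failed to improve for `patience + 1` consecutive epochs.
#' @param seed seed for initialization and shuffling.
#' @param strict_pool collapse the conv block to one channel (`D x 1`).
#' @param max_train_windows,max_val_windows optional caps; when set, an
#'   evenly spaced deterministic subsample of windows is used (a
#'   desk-scale control, not part of the method).
#' @return an object of class `convformer_config`.
#' @export
convformer_config <- function(window_d = 96L, horizon_tau = 24L,
                              conv_kernel = c(3L, 3L), conv_channels = 64L,
                              d_model = 64L, n_heads = 4L, n_layers = 2L,
                              d_ff = NULL, dropout = 0,
                              loss = "mse", optimizer = "adam",
                              learning_rate = 1e-3, batch_size = 32L,
                              max_epochs = 20L, patience = 3L, seed = 1L,
                              strict_pool = FALSE,
                              max_train_windows = NULL,
                              max_val_windows = NULL) {
  assert_count(window_d, "window_d"); assert_count(horizon_tau, "horizon_tau")
  assert_count(conv_channels, "conv_channels")
  assert_count(d_model, "d_model"); assert_count(n_heads, "n_heads")
  assert_count(n_layers, "n_layers")
  assert_count(batch_size, "batch_size"); assert_count(max_epochs, "max_epochs")
  assert_count(patience, "patience", min = 0L)
  assert_prob(dropout, "dropout", open = FALSE)
  if (length(conv_kernel) != 2L || any(conv_kernel < 1)) {
    stop_config("conv_kernel must be two positive integers c(p, q)")
  }
  if (conv_kernel[1] > window_d) {
    stop_config("kernel time extent p = %d exceeds window_d = %d",
                conv_kernel[1], window_d)
  }
  if (d_model %% n_heads != 0) {
    stop_config("n_heads (%d) must divide d_model (%d)", n_heads, d_model)
  }
  loss <- match.arg(loss, "mse"); optimizer <- match.arg(optimizer, "adam")
  structure(list(window_d = as.integer(window_d),
                 horizon_tau = as.integer(horizon_tau),
                 conv_kernel = as.integer(conv_kernel),
                 conv_channels = if (strict_pool) 1L else as.integer(conv_channels),
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers),
                 d_ff = as.integer(d_ff %||% (2L * d_model)),
                 dropout = dropout, loss = loss, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 strict_pool = isTRUE(strict_pool),
                 max_train_windows = max_train_windows,
                 max_val_windows = max_val_windows),
            class = "convformer_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

positional_encoding <- function(D, dm) {
  pe <- matrix(0, D, dm)
  pos <- seq_len(D)
  for (i in seq_len(ceiling(dm / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / dm)
    pe[, 2 * i - 1] <- sin(pos * freq)
    if (2 * i <= dm) pe[, 2 * i] <- cos(pos * freq)
  }
  pe
}

#' Build a ConvFormer model
#'
#' @param config a [convformer_config()].
#' @param n_features number of input features M (window columns).
#' @return an object of class `convformer_model` (config, parameter list,
#'   fixed positional encoding).
#' @export
build_convformer <- function(config, n_features) {
  stopifnot(inherits(config, "convformer_config"))
  assert_count(n_features, "n_features")
  if (config$conv_kernel[2] > n_features) {
    stop_config("kernel feature extent q = %d exceeds n_features = %d",
                config$conv_kernel[2], n_features)
  }
  set.seed(derive_seed(config$seed, 31L))
  p <- config$conv_kernel[1]; q <- config$conv_kernel[2]
  C <- config$conv_channels; dm <- config$d_model
  params <- list(
    conv_w = array(stats::runif(p * q * C, -sqrt(6 / (p * q + C)),
                                sqrt(6 / (p * q + C))), dim = c(p, q, C)),
    conv_b = rep(0, C),
    Win = glorot(C, dm), bin = rep(0, dm),
    Wout = glorot(config$window_d * dm, config$horizon_tau),
    bout = rep(0, config$horizon_tau))
  for (l in seq_len(config$n_layers)) {
    params[[paste0("Wq", l)]] <- glorot(dm, dm)
    params[[paste0("Wk", l)]] <- glorot(dm, dm)
    params[[paste0("Wv", l)]] <- glorot(dm, dm)
    params[[paste0("Wo", l)]] <- glorot(dm, dm)
    params[[paste0("bq", l)]] <- rep(0, dm)
    params[[paste0("bk", l)]] <- rep(0, dm)
    params[[paste0("bv", l)]] <- rep(0, dm)
    params[[paste0("bo", l)]] <- rep(0, dm)
    params[[paste0("ln1g", l)]] <- rep(1, dm)
    params[[paste0("ln1b", l)]] <- rep(0, dm)
    params[[paste0("W1", l)]] <- glorot(dm, config$d_ff)
    params[[paste0("b1", l)]] <- rep(0, config$d_ff)
    params[[paste0("W2", l)]] <- glorot(config$d_ff, dm)
    params[[paste0("b2", l)]] <- rep(0, dm)
    params[[paste0("ln2g", l)]] <- rep(1, dm)
    params[[paste0("ln2b", l)]] <- rep(0, dm)
  }
  structure(list(config = config, params = params,
                 pe = positional_encoding(config$window_d, dm),
                 n_features = as.integer(n_features)),
            class = "convformer_model")
}

#' Convolution + max-pooling feature block
#'
#' Each feature-map element is
#' `activation(sum_{m,n} w[m, n] * x[i + m, j + n] + b)` with zero padding
#' at the trailing edges so the map keeps the `D x M` shape; max pooling
#' then collapses the feature axis, leaving one value per time step per
#' channel.
#'
#' @param x_window `D x M` numeric matrix (no non-finite values).
#' @param w kernel array `p x q x channels` (a `p x q` matrix is treated
#'   as one channel).
#' @param b per-channel bias vector.
#' @param activation `"relu"` or `"identity"`.
#' @return `D x channels` matrix of pooled features.
#' @export
conv_block <- function(x_window, w, b, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (!all(is.finite(x_window))) stop_config("window contains non-finite values")
  if (length(dim(w)) == 2L) w <- array(w, dim = c(dim(w), 1L))
  conv_block_fwd(as.matrix(x_window), w, b, relu = activation == "relu")$P
}

conv_block_fwd <- function(X, w, b, relu = TRUE) {
  D <- nrow(X); M <- ncol(X)
  p <- dim(w)[1]; q <- dim(w)[2]; C <- dim(w)[3]
  Xpad <- matrix(0, D + p - 1L, M + q - 1L)
  Xpad[seq_len(D), seq_len(M)] <- X
  Z <- array(0, dim = c(D, M, C))
  for (cc in seq_len(C)) {
    Zc <- matrix(b[cc], D, M)
    for (m in seq_len(p)) for (n in seq_len(q)) {
      Zc <- Zc + w[m, n, cc] *
        Xpad[m:(m + D - 1L), n:(n + M - 1L), drop = FALSE]
    }
    Z[, , cc] <- Zc
  }
  A <- if (relu) pmax(Z, 0) else Z
  P <- matrix(0, D, C)
  amax <- matrix(1L, D, C)
  for (cc in seq_len(C)) {
    Ac <- A[, , cc, drop = FALSE]
    dim(Ac) <- c(D, M)
    amax[, cc] <- max.col(Ac, ties.method = "first")
    P[, cc] <- Ac[cbind(seq_len(D), amax[, cc])]
  }
  list(P = P, Z = Z, amax = amax, Xpad = Xpad, relu = relu)
}

conv_block_bwd <- function(cache, dP, w) {
  D <- nrow(dP); C <- ncol(dP)
  p <- dim(w)[1]; q <- dim(w)[2]; M <- dim(cache$Z)[2]
  dw <- array(0, dim = dim(w)); db <- numeric(C)
  for (cc in seq_len(C)) {
    dZ <- matrix(0, D, M)
    act <- dP[, cc]
    if (cache$relu) {
      zsel <- cache$Z[cbind(seq_len(D), cache$amax[, cc], cc)]
      act <- act * (zsel > 0)
    }
    dZ[cbind(seq_len(D), cache$amax[, cc])] <- act
    db[cc] <- sum(dZ)
    for (m in seq_len(p)) for (n in seq_len(q)) {
      dw[m, n, cc] <- sum(dZ * cache$Xpad[m:(m + D - 1L),
                                          n:(n + M - 1L), drop = FALSE])
    }
  }
  list(dw = dw, db = db)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`; each weight row sums to one.
#'
#' @param Q,K,V matrices with the same number of rows (sequence length);
#'   `Q` and `K` share the key width `d_k`.
#' @return list with `output` and the row-stochastic `weights`.
#' @export
attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(ncol(K))
  W <- softmax_rows(S)
  list(output = W %*% V, weights = W)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv_sigma <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv_sigma
  Y <- sweep(xhat, 2, g, "*")
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, xhat = xhat, inv_sigma = inv_sigma)
}

layernorm_bwd <- function(cache, dY, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv_sigma
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

add_bias <- function(X, b) sweep(X, 2, b, "+")

# Forward pass for one sample; returns prediction and (optionally) every
# intermediate needed by the backward pass.
cf_forward <- function(model, X, keep_cache = FALSE, drop_masks = NULL) {
  cfg <- model$config; pp <- model$params
  cache <- if (keep_cache) list() else NULL
  cb <- conv_block_fwd(X, pp$conv_w, pp$conv_b, relu = TRUE)
  H <- add_bias(cb$P %*% pp$Win, pp$bin) + model$pe
  if (keep_cache) { cache$cb <- cb; cache$P <- cb$P }
  dm <- cfg$d_model; nh <- cfg$n_heads; dk <- dm %/% nh
  for (l in seq_len(cfg$n_layers)) {
    Q <- add_bias(H %*% pp[[paste0("Wq", l)]], pp[[paste0("bq", l)]])
    K <- add_bias(H %*% pp[[paste0("Wk", l)]], pp[[paste0("bk", l)]])
    V <- add_bias(H %*% pp[[paste0("Wv", l)]], pp[[paste0("bv", l)]])
    O <- matrix(0, nrow(H), dm)
    Ws <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
      W <- softmax_rows(S)
      O[, cols] <- W %*% V[, cols, drop = FALSE]
      Ws[[h]] <- W
    }
    Oo <- add_bias(O %*% pp[[paste0("Wo", l)]], pp[[paste0("bo", l)]])
    mask1 <- NULL
    if (!is.null(drop_masks)) {
      mask1 <- drop_masks[[l]]$m1
      Oo <- Oo * mask1
    }
    ln1 <- layernorm_fwd(H + Oo, pp[[paste0("ln1g", l)]],
                         pp[[paste0("ln1b", l)]])
    H1 <- ln1$Y
    U <- add_bias(H1 %*% pp[[paste0("W1", l)]], pp[[paste0("b1", l)]])
    R <- pmax(U, 0)
    Fo <- add_bias(R %*% pp[[paste0("W2", l)]], pp[[paste0("b2", l)]])
    mask2 <- NULL
    if (!is.null(drop_masks)) {
      mask2 <- drop_masks[[l]]$m2
      Fo <- Fo * mask2
    }
    ln2 <- layernorm_fwd(H1 + Fo, pp[[paste0("ln2g", l)]],
                         pp[[paste0("ln2b", l)]])
    if (keep_cache) {
      cache[[paste0("layer", l)]] <- list(
        H_in = H, Q = Q, K = K, V = V, O = O, Ws = Ws, ln1 = ln1, H1 = H1,
        U = U, R = R, mask1 = mask1, mask2 = mask2)
    }
    H <- ln2$Y
    if (keep_cache) cache[[paste0("layer", l)]]$ln2 <- ln2
  }
  v <- as.vector(H)
  y <- drop(v %*% pp$Wout) + pp$bout
  if (keep_cache) { cache$v <- v; cache$H_final <- H }
  list(y = y, cache = cache)
}

# Backward pass for one sample; dy is dLoss/dy (length tau).
cf_backward <- function(model, cache, dy) {
  cfg <- model$config; pp <- model$params
  dm <- cfg$d_model; nh <- cfg$n_heads; dk <- dm %/% nh
  g <- list()
  g$Wout <- outer(cache$v, dy)
  g$bout <- dy
  dH <- matrix(pp$Wout %*% dy, nrow(cache$H_final), dm)
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache[[paste0("layer", l)]]
    ln2b <- layernorm_bwd(lc$ln2, dH, pp[[paste0("ln2g", l)]])
    g[[paste0("ln2g", l)]] <- ln2b$dg; g[[paste0("ln2b", l)]] <- ln2b$db
    dsum2 <- ln2b$dX
    dH1 <- dsum2
    dFo <- dsum2
    if (!is.null(lc$mask2)) dFo <- dFo * lc$mask2
    g[[paste0("W2", l)]] <- t(lc$R) %*% dFo
    g[[paste0("b2", l)]] <- colSums(dFo)
    dR <- dFo %*% t(pp[[paste0("W2", l)]])
    dU <- dR * (lc$U > 0)
    g[[paste0("W1", l)]] <- t(lc$H1) %*% dU
    g[[paste0("b1", l)]] <- colSums(dU)
    dH1 <- dH1 + dU %*% t(pp[[paste0("W1", l)]])
    ln1b <- layernorm_bwd(lc$ln1, dH1, pp[[paste0("ln1g", l)]])
    g[[paste0("ln1g", l)]] <- ln1b$dg; g[[paste0("ln1b", l)]] <- ln1b$db
    dsum1 <- ln1b$dX
    dH_in <- dsum1
    dOo <- dsum1
    if (!is.null(lc$mask1)) dOo <- dOo * lc$mask1
    g[[paste0("Wo", l)]] <- t(lc$O) %*% dOo
    g[[paste0("bo", l)]] <- colSums(dOo)
    dO <- dOo %*% t(pp[[paste0("Wo", l)]])
    dQ <- matrix(0, nrow(dO), dm); dK <- dQ; dV <- dQ
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      W <- lc$Ws[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- lc$V[, cols, drop = FALSE]
      dWa <- dOh %*% t(Vh)
      dV[, cols] <- t(W) %*% dOh
      dS <- W * (dWa - rowSums(dWa * W))
      dQ[, cols] <- dS %*% lc$K[, cols, drop = FALSE] / sqrt(dk)
      dK[, cols] <- t(dS) %*% lc$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    g[[paste0("Wq", l)]] <- t(lc$H_in) %*% dQ
    g[[paste0("bq", l)]] <- colSums(dQ)
    g[[paste0("Wk", l)]] <- t(lc$H_in) %*% dK
    g[[paste0("bk", l)]] <- colSums(dK)
    g[[paste0("Wv", l)]] <- t(lc$H_in) %*% dV
    g[[paste0("bv", l)]] <- colSums(dV)
    dH <- dH_in + dQ %*% t(pp[[paste0("Wq", l)]]) +
      dK %*% t(pp[[paste0("Wk", l)]]) + dV %*% t(pp[[paste0("Wv", l)]])
  }
  # input projection and conv block
  g$Win <- t(cache$P) %*% dH
  g$bin <- colSums(dH)
  dP <- dH %*% t(pp$Win)
  cb <- conv_block_bwd(cache$cb, dP, pp$conv_w)
  g$conv_w <- cb$dw; g$conv_b <- cb$db
  g
}

#' Forward pass of a built model on one input window
#'
#' @param model a `convformer_model`.
#' @param x_window `D x M` matrix in scaled units.
#' @return numeric vector of length `horizon_tau` (scaled units).
#' @export
forward_convformer <- function(model, x_window) {
  stopifnot(inherits(model, "convformer_model"))
  x_window <- as.matrix(x_window)
  if (!all(is.finite(x_window))) stop_config("window contains non-finite values")
  if (nrow(x_window) != model$config$window_d ||
      ncol(x_window) != model$n_features) {
    stop_config("window shape %d x %d does not match model (%d x %d)",
                nrow(x_window), ncol(x_window),
                model$config$window_d, model$n_features)
  }
  cf_forward(model, x_window)$y
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

subsample_idx <- function(n, cap) {
  if (is.null(cap) || n <= cap) return(seq_len(n))
  unique(round(seq(1, n, length.out = cap)))
}

#' Train a ConvFormer on a windowed dataset
#'
#' Minimizes mean squared error over all tau outputs with Adam and early
#' stopping on validation loss; the best-validation weights are restored.
#'
#' @param model a `convformer_model` from [build_convformer()].
#' @param windowed a `windowed_dataset` from [split_and_window()].
#' @param verbose print per-epoch losses.
#' @return the trained model, with `$history` (per-epoch train/val loss)
#'   and `$best_epoch` attached.
#' @export
train_convformer <- function(model, windowed, verbose = FALSE) {
  stopifnot(inherits(model, "convformer_model"),
            inherits(windowed, "windowed_dataset"))
  cfg <- model$config
  tr_rows <- which(windowed$index$split == "train")
  va_rows <- which(windowed$index$split == "val")
  if (!length(tr_rows) || !length(va_rows)) {
    stop_config("training and validation splits must both be non-empty")
  }
  tr_keep <- subsample_idx(length(tr_rows), cfg$max_train_windows)
  va_keep <- subsample_idx(length(va_rows), cfg$max_val_windows)
  tr <- get_windows(windowed, "train",
                    indices = tr_keep)
  va <- get_windows(windowed, "val", indices = va_keep)
  n_tr <- dim(tr$inputs)[1]

  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  use_dropout <- cfg$dropout > 0

  for (epoch in seq_len(cfg$max_epochs)) {
    set.seed(derive_seed(cfg$seed, 40L + epoch))
    ord <- sample.int(n_tr)
    ep_loss <- 0; n_seen <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      grads <- NULL
      batch_loss <- 0
      for (i in bs) {
        X <- tr$inputs[i, , , drop = TRUE]
        dim(X) <- c(cfg$window_d, dim(tr$inputs)[3])
        masks <- NULL
        if (use_dropout) {
          masks <- lapply(seq_len(cfg$n_layers), function(l) list(
            m1 = matrix(stats::rbinom(cfg$window_d * cfg$d_model, 1,
                                      1 - cfg$dropout) / (1 - cfg$dropout),
                        cfg$window_d, cfg$d_model),
            m2 = matrix(stats::rbinom(cfg$window_d * cfg$d_model, 1,
                                      1 - cfg$dropout) / (1 - cfg$dropout),
                        cfg$window_d, cfg$d_model)))
        }
        fw <- cf_forward(model, X, keep_cache = TRUE, drop_masks = masks)
        err <- fw$y - tr$targets[i, ]
        batch_loss <- batch_loss + mean(err^2)
        gi <- cf_backward(model, fw$cache, 2 * err / cfg$horizon_tau)
        grads <- if (is.null(grads)) gi else
          Map(`+`, grads, gi[names(grads)])
      }
      nb <- length(bs)
      grads <- lapply(grads, `/`, nb)
      if (!all(vapply(grads, function(x) all(is.finite(x)), TRUE))) {
        stop("non-finite gradient encountered; lower the learning rate",
             call. = FALSE)
      }
      upd <- adam_step(params, grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
      model$params <- params
      ep_loss <- ep_loss + batch_loss; n_seen <- n_seen + nb
    }
    train_loss <- ep_loss / n_seen
    if (!is.finite(train_loss)) {
      stop(sprintf("non-finite training loss at epoch %d", epoch),
           call. = FALSE)
    }
    val_loss <- dataset_loss(model, va)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) cf_log("info", "epoch %d: train %.5f val %.5f",
                        epoch, train_loss, val_loss)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > cfg$patience) break
    }
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

dataset_loss <- function(model, data) {
  n <- dim(data$inputs)[1]
  tot <- 0
  for (i in seq_len(n)) {
    X <- data$inputs[i, , , drop = TRUE]
    dim(X) <- c(dim(data$inputs)[2], dim(data$inputs)[3])
    y <- cf_forward(model, X)$y
    tot <- tot + mean((y - data$targets[i, ])^2)
  }
  tot / n
}

#' Point predictions on a split, in original units
#'
#' Runs the trained model over all windows of the requested split and
#' inverse-scales predictions; actual target rows are taken from the
#' unscaled panel, and residuals are `actual - prediction` per horizon
#' step.
#'
#' @param model trained `convformer_model`.
#' @param windowed the `windowed_dataset` used in training.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @param max_windows optional evenly spaced subsample cap (desk-scale
#'   control).
#' @return an object of class `forecast_result`: `$point_predictions` and
#'   `$actuals` (`n x tau`, original units), `$residuals`, `$t`, `$split`.
#' @export
predict_convformer <- function(model, windowed, split = "test",
                               max_windows = NULL) {
  stopifnot(inherits(model, "convformer_model"),
            inherits(windowed, "windowed_dataset"))
  rows <- which(windowed$index$split == split)
  keep <- subsample_idx(length(rows), max_windows)
  data <- get_windows(windowed, split, indices = keep)
  n <- dim(data$inputs)[1]
  tau <- model$config$horizon_tau
  preds <- matrix(0, n, tau)
  for (i in seq_len(n)) {
    X <- data$inputs[i, , , drop = TRUE]
    dim(X) <- c(dim(data$inputs)[2], dim(data$inputs)[3])
    preds[i, ] <- cf_forward(model, X)$y
  }
  preds <- invert_scaler(preds, windowed$scaler, feature = windowed$target)
  actuals <- matrix(0, n, tau)
  for (i in seq_len(n)) {
    t <- data$t[i]
    actuals[i, ] <- windowed$raw_values[(t + 1L):(t + tau),
                                        windowed$target_col]
  }
  structure(list(point_predictions = preds, actuals = actuals,
                 residuals = actuals - preds, t = data$t, split = split),
            class = "forecast_result")
}

#' Save / load a model checkpoint as JSON
#'
#' Plain-text checkpoint embedding the config, so a saved model can be
#' reloaded without any binary artefacts.
#'
#' @param model a `convformer_model`.
#' @param path JSON file path.
#' @return `write_checkpoint` the path, `read_checkpoint` the model.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "convformer_model"))
  obj <- list(config = unclass(model$config),
              n_features = model$n_features,
              params = lapply(model$params, function(p) {
                list(dim = dim(p) %||% length(p), data = as.vector(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- obj$config
  cfg_args$conv_kernel <- as.integer(cfg_args$conv_kernel)
  cfg <- do.call(convformer_config, cfg_args[names(cfg_args) %in%
                                               names(formals(convformer_config))])
  model <- build_convformer(cfg, obj$n_features)
  for (nm in names(model$params)) {
    p <- obj$params[[nm]]
    dm <- unlist(p$dim)
    v <- as.numeric(unlist(p$data))
    model$params[[nm]] <- if (length(dm) > 1L) array(v, dim = dm) else v
  }
  model
}
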