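# Shared fixtures and independent oracles. Oracles deliberately re-derive
# results with plain loops / direct formulas, not via package internals.

tiny_synth <- function(seed = 1L, n_hours = 2000L, n_stations = 6L, ...) {
  synth_config(n_stations = n_stations, n_poi = 300L, n_hours = n_hours,
               seed = seed, ...)
}

# Brute-force normalized Euclidean (own loop, not the package function)
oracle_ned <- function(a, b, s) {
  tot <- 0
  for (k in seq_along(a)) {
    if (s[k] > 0) tot <- tot + ((a[k] - b[k]) / s[k])^2
  }
  sqrt(tot)
}

# Exhaustive O(N^3) average-linkage re-scan: recomputes every cluster pair
# distance from the raw profiles at every step; lexicographic tie-break on
# current positions, merged cluster replaces position i, position j removed.
oracle_hclust <- function(profiles) {
  N <- nrow(profiles)
  s <- apply(profiles, 2, stats::sd)
  clusters <- lapply(seq_len(N), identity)
  history <- list()
  while (length(clusters) > 1L) {
    n <- length(clusters)
    D <- matrix(Inf, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      tot <- 0; cnt <- 0L
      for (a in clusters[[i]]) for (b in clusters[[j]]) {
        tot <- tot + oracle_ned(profiles[a, ], profiles[b, ], s)
        cnt <- cnt + 1L
      }
      D[i, j] <- tot / cnt
    }
    # lexicographically first pair within float tolerance of the minimum
    m0 <- min(D)
    thresh <- m0 + 1e-9 * (1 + abs(m0))
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (D[i, j] <= thresh) { best <- c(i, j); break }
      }
      if (!is.null(best)) break
    }
    history[[length(history) + 1L]] <- list(a = clusters[[best[1]]],
                                            b = clusters[[best[2]]],
                                            distance = D[best[1], best[2]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  history
}

# Four-nested-loop convolution + pooling, zero padding at trailing edges.
oracle_conv <- function(X, w, b, relu = TRUE) {
  D <- nrow(X); M <- ncol(X)
  p <- dim(w)[1]; q <- dim(w)[2]; C <- dim(w)[3]
  P <- matrix(0, D, C)
  for (cc in seq_len(C)) {
    A <- matrix(0, D, M)
    for (i in seq_len(D)) for (j in seq_len(M)) {
      acc <- b[cc]
      for (m in seq_len(p)) for (n in seq_len(q)) {
        ii <- i + m - 1L; jj <- j + n - 1L
        if (ii <= D && jj <= M) acc <- acc + w[m, n, cc] * X[ii, jj]
      }
      A[i, j] <- if (relu) max(acc, 0) else acc
    }
    P[, cc] <- apply(A, 1, max)
  }
  P
}

# hand-made series panel with optional missingness
make_panel <- function(values, mask = NULL) {
  ts <- as.POSIXct("2021-01-01", tz = "UTC") + 3600 * (seq_len(nrow(values)) - 1)
  series_panel(ts, values, mask)
}

# hand-made forecast result
make_forecast <- function(pred, actual, split = "train") {
  structure(list(point_predictions = pred, actuals = actual,
                 residuals = actual - pred,
                 t = seq_len(nrow(pred)), split = split),
            class = "forecast_result")
}

tiny_model_cfg <- function(...) {
  args <- utils::modifyList(
    list(window_d = 12L, horizon_tau = 4L, conv_kernel = c(2L, 2L),
         conv_channels = 4L, d_model = 8L, n_heads = 2L, n_layers = 1L,
         d_ff = 12L, batch_size = 16L, max_epochs = 3L, patience = 1L,
         seed = 5L),
    list(...))
  do.call(convformer_config, args)
}

# small windowed dataset over a deterministic learnable series
sine_windowed <- function(T_ = 400L, D = 24L, tau = 4L, n_extra = 1L,
                          seed = 2L) {
  set.seed(seed)
  base <- 20 + 10 * sin(2 * pi * seq_len(T_) / 24)
  vals <- cbind(PM2.5 = base,
                matrix(runif(T_ * n_extra, 0, 50), ncol = n_extra,
                       dimnames = list(NULL, paste0("X", seq_len(n_extra)))))
  split_and_window(make_panel(vals), D = D, tau = tau)
}
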