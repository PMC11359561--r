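test_that("error collection: perfect forecast, constant bias, sign convention", {
  act <- matrix(runif(20, 10, 20), 5, 4)
  fc0 <- make_forecast(act, act)
  d0 <- collect_errors(fc0)
  expect_true(all(vapply(d0$errors, function(e) all(e == 0), TRUE)))
  fc2 <- make_forecast(act - 2, act)   # predictions 2 below actuals
  d2 <- collect_errors(fc2)
  expect_true(all(vapply(d2$errors, function(e) all(e == 2), TRUE)))
  # error = actual - predicted = residual
  expect_equal(mean(d2$errors[[1]]), mean(fc2$residuals[, 1]))
  pooled <- collect_errors(fc2, pooled = TRUE)
  expect_length(pooled$errors, 1L)
  expect_length(pooled$errors[[1]], 20L)
})

test_that("Gaussian KDE pdf and cdf closed forms", {
  expect_equal(kde_pdf(0, 1, 0), 1 / sqrt(2 * pi))
  set.seed(60)
  e <- rnorm(200, 2, 3)
  h <- 0.5
  xs <- seq(-12, 16, length.out = 400)
  cdf <- kde_cdf(e, h, xs)
  expect_true(all(diff(cdf) >= 0))
  expect_lt(cdf[1], 1e-4)
  expect_gt(cdf[length(xs)], 1 - 1e-4)
  expect_equal(kde_cdf(e, h, -1e6), 0, tolerance = 1e-12)
  expect_equal(kde_cdf(e, h, 1e6), 1, tolerance = 1e-12)

  # pdf integrates to 1 (trapezoid over a wide grid)
  grid <- seq(min(e) - 8 * h, max(e) + 8 * h, length.out = 4000)
  pdf <- kde_pdf(e, h, grid)
  area <- sum(diff(grid) * (pdf[-1] + pdf[-length(pdf)]) / 2)
  expect_lt(abs(area - 1), 1e-4)

  # closed-form cdf equals quadrature of the pdf
  for (x0 in c(-2, 1, 4.5)) {
    g2 <- seq(min(e) - 10 * h, x0, length.out = 20000)
    p2 <- kde_pdf(e, h, g2)
    quad <- sum(diff(g2) * (p2[-1] + p2[-length(p2)]) / 2)
    expect_lt(abs(quad - kde_cdf(e, h, x0)), 1e-6)
  }
})

test_that("bandwidth selection: Silverman neighbourhood, degenerate grid, duplication", {
  set.seed(61)
  e <- rnorm(1000)
  h_ref <- 1.06 * sd(e) * 1000^(-1 / 5)
  h <- select_bandwidth(e, seed = 2)
  expect_gt(h, h_ref / 2)
  expect_lt(h, h_ref * 2)
  expect_equal(select_bandwidth(e, grid = 0.37), 0.37)
  expect_error(select_bandwidth(rnorm(5)), ">= 10")
  # duplicating every sample point leaves the estimated density — and
  # therefore any likelihood ordering over bandwidths — exactly unchanged
  xs <- seq(-3, 3, length.out = 50)
  for (hh in c(0.1, 0.3, 1)) {
    expect_equal(kde_pdf(c(e, e), hh, xs), kde_pdf(e, hh, xs))
    expect_equal(kde_cdf(c(e, e), hh, xs), kde_cdf(e, hh, xs))
  }
})

test_that("quantiles: inversion, symmetry, normal reference", {
  set.seed(62)
  e <- rnorm(500, 1, 2)
  h <- silverman_bandwidth(e)
  for (p in c(0.025, 0.5, 0.975)) {
    q <- convformer:::kde_quantile(e, h, p)
    expect_lt(abs(kde_cdf(e, h, q) - p), 1e-6)
  }
  # symmetrized sample gives l = -u
  es <- c(e, -e)
  q <- error_quantiles(es, h, 0.9)
  expect_equal(q[1], -q[2], tolerance = 1e-6)
  # monotonicity in alpha
  q_small <- error_quantiles(e, h, 0.5)
  q_big <- error_quantiles(e, h, 0.99)
  expect_lt(q_big[1], q_small[1])
  expect_gt(q_big[2], q_small[2])

  set.seed(63)
  big <- rnorm(10000)
  hb <- select_bandwidth(big[1:2000], seed = 3)
  u <- error_quantiles(big, hb, 0.95)[2]
  expect_gte(u, 1.85)
  expect_lte(u, 2.10)
})

test_that("interval construction: shift arithmetic, nesting, constant width", {
  set.seed(64)
  pred <- matrix(runif(30, 20, 40), 10, 3)
  act <- pred + rnorm(30)
  fc <- make_forecast(pred, act, split = "test")
  errs <- replicate(3, rnorm(300, 0, 2), simplify = FALSE)
  dist <- structure(list(errors = errs, pooled = FALSE, split = "train",
                         bandwidths = rep(0.4, 3)),
                    class = "error_distribution")
  iv <- build_intervals(fc, dist, alphas = c(0.85, 0.90, 0.95))
  for (key in names(iv$bounds)) {
    b <- iv$bounds[[key]]; off <- iv$offsets[[key]]
    expect_equal(b$lower, sweep(pred, 2, off$l, "+"))
    expect_equal(b$upper, sweep(pred, 2, off$u, "+"))
    expect_true(all(b$lower <= b$upper))
    # additive construction: constant width per horizon step
    w <- b$upper - b$lower
    expect_equal(w, matrix(rep(off$u - off$l, each = 10), 10, 3))
  }
  # nesting across confidence levels
  expect_true(all(iv$bounds$a85$lower >= iv$bounds$a90$lower))
  expect_true(all(iv$bounds$a90$lower >= iv$bounds$a95$lower))
  expect_true(all(iv$bounds$a85$upper <= iv$bounds$a90$upper))
  expect_true(all(iv$bounds$a90$upper <= iv$bounds$a95$upper))
})

test_that("coverage: stationary errors give PICP >= alpha - 0.02 over 20 seeds", {
  alphas <- c(0.85, 0.90, 0.95)
  cov_mat <- t(vapply(1:20, function(s) {
    set.seed(s)
    n_fit <- 400L; n_test <- 400L; tau <- 2L
    noise_sd <- 3
    pred_fit <- matrix(runif(n_fit * tau, 10, 30), n_fit, tau)
    act_fit <- pred_fit + matrix(rnorm(n_fit * tau, 0, noise_sd), n_fit, tau)
    pred_te <- matrix(runif(n_test * tau, 10, 30), n_test, tau)
    act_te <- pred_te + matrix(rnorm(n_test * tau, 0, noise_sd), n_test, tau)
    dist <- collect_errors(make_forecast(pred_fit, act_fit))
    dist <- fit_error_kde(dist, max_errors = 400L, seed = s)
    iv <- build_intervals(make_forecast(pred_te, act_te, split = "test"),
                          dist, alphas = alphas)
    vapply(names(iv$bounds), function(k) {
      picp(as.vector(act_te), as.vector(iv$bounds[[k]]$lower),
           as.vector(iv$bounds[[k]]$upper))
    }, numeric(1))
  }, numeric(3)))
  mean_cov <- colMeans(cov_mat)
  expect_gte(mean_cov[["a85"]], 0.83)
  expect_gte(mean_cov[["a90"]], 0.88)
  expect_gte(mean_cov[["a95"]], 0.93)
})
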