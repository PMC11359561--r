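# Gaussian kernel density estimation of point-forecast errors and the
# equal-tailed prediction intervals derived from it. The KDE cdf is the
# closed-form mixture of normal cdfs (no numerical integration); quantiles
# are found by bisection on that monotone cdf. The bandwidth is chosen by
# maximizing mean held-out log-likelihood over a log-spaced grid with
# 5-fold cross-validation.

#' Collect point-forecast errors per horizon step
#'
#' Errors are `actual - predicted` in original units, taken by default
#' from the training split (the split the interval distribution is fitted
#' on; fitting on validation instead is supported because training
#' residuals can understate test error).
#'
#' @param forecast a `forecast_result` (computed on the source split).
#' @param pooled collapse all horizon steps into one error sample instead
#'   of keeping one sample per step.
#' @return an object of class `error_distribution`: `$errors` (list of
#'   per-step numeric vectors, or a single pooled vector), `$pooled`,
#'   `$split`; bandwidths are attached by [select_bandwidth()].
#' @export
collect_errors <- function(forecast, pooled = FALSE) {
  stopifnot(inherits(forecast, "forecast_result"))
  if (!nrow(forecast$actuals)) stop_config("empty split: no errors to collect")
  err <- forecast$actuals - forecast$point_predictions
  errors <- if (pooled) list(as.vector(err)) else
    lapply(seq_len(ncol(err)), function(j) err[, j])
  structure(list(errors = errors, pooled = pooled, split = forecast$split,
                 bandwidths = NULL), class = "error_distribution")
}

#' Silverman reference bandwidth
#'
#' `1.06 * sd(x) * n^(-1/5)`, the normal-reference rule the search grid is
#' centred on.
#'
#' @param x numeric sample.
#' @return positive scalar.
#' @export
silverman_bandwidth <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- max(abs(x), 1e-3)
  1.06 * s * length(x)^(-1 / 5)
}

#' Gaussian KDE density and distribution function
#'
#' `kde_pdf(x) = mean(dnorm((x - e_i) / h)) / h`;
#' `kde_cdf(x) = mean(pnorm((x - e_i) / h))` — the exact cdf of the
#' Gaussian mixture, no quadrature involved.
#'
#' @param errors numeric sample the KDE is centred on.
#' @param h bandwidth, `> 0`.
#' @param x evaluation point(s).
#' @return numeric vector the length of `x`.
#' @export
kde_pdf <- function(errors, h, x) {
  stopifnot(h > 0, length(errors) >= 1)
  vapply(x, function(xi) mean(stats::dnorm((xi - errors) / h)) / h,
         numeric(1))
}

#' @rdname kde_pdf
#' @export
kde_cdf <- function(errors, h, x) {
  stopifnot(h > 0, length(errors) >= 1)
  vapply(x, function(xi) mean(stats::pnorm((xi - errors) / h)), numeric(1))
}

cv_loglik <- function(errors, h, folds) {
  tot <- 0
  for (f in folds) {
    held <- errors[f]; rest <- errors[-f]
    d <- kde_pdf(rest, h, held)
    if (any(d <= 0)) return(-Inf)
    tot <- tot + sum(log(d))
  }
  tot / length(errors)
}

#' Cross-validated grid search for the KDE bandwidth
#'
#' Maximizes the mean held-out log-likelihood over a 5-fold shuffled split
#' (fixed seed). The default grid is 25 log-spaced points spanning
#' `[h_ref / 10, h_ref * 10]` around the Silverman reference bandwidth.
#' If every candidate scores `-Inf` the grid is widened by a factor of 10
#' once, then the search fails.
#'
#' @param errors numeric sample (at least 10 points).
#' @param grid optional bandwidth grid.
#' @param n_folds number of CV folds.
#' @param seed seed for the fold shuffle.
#' @return the selected bandwidth (`h_opt`); ties go to the smaller h.
#' @export
select_bandwidth <- function(errors, grid = NULL, n_folds = 5L, seed = 1L) {
  errors <- errors[is.finite(errors)]
  if (length(errors) < 10L) stop_config("need >= 10 error samples, got %d",
                                        length(errors))
  h_ref <- silverman_bandwidth(errors)
  if (is.null(grid)) {
    grid <- exp(seq(log(h_ref / 10), log(h_ref * 10), length.out = 25L))
  }
  if (length(grid) == 1L) return(grid)
  set.seed(derive_seed(seed, 51L))
  idx <- sample.int(length(errors))
  folds <- split(idx, cut(seq_along(idx), breaks = n_folds, labels = FALSE))
  ll <- vapply(grid, function(h) cv_loglik(errors, h, folds), numeric(1))
  if (all(!is.finite(ll))) {
    grid <- exp(seq(log(h_ref / 100), log(h_ref * 100), length.out = 25L))
    ll <- vapply(grid, function(h) cv_loglik(errors, h, folds), numeric(1))
    if (all(!is.finite(ll))) {
      stop_config("bandwidth selection failed: all candidates give -Inf likelihood")
    }
  }
  grid[which.max(ll)]
}

#' Fit bandwidths for an error distribution
#'
#' Runs [select_bandwidth()] on each per-step error sample (or the pooled
#' sample). Large samples may be subsampled deterministically via
#' `max_errors` to bound the CV cost.
#'
#' @param dist an `error_distribution`.
#' @param max_errors cap on the sample used for bandwidth CV.
#' @param seed seed passed to [select_bandwidth()].
#' @return the `error_distribution` with `$bandwidths` filled.
#' @export
fit_error_kde <- function(dist, max_errors = 2000L, seed = 1L) {
  stopifnot(inherits(dist, "error_distribution"))
  dist$bandwidths <- vapply(dist$errors, function(e) {
    keep <- subsample_idx(length(e), max_errors)
    select_bandwidth(e[keep], seed = seed)
  }, numeric(1))
  dist
}

#' Equal-tailed error quantiles from the KDE
#'
#' Inverts the closed-form KDE cdf by bisection (tolerance `1e-8` on the
#' error axis) at probabilities `(1 - alpha) / 2` and `(1 + alpha) / 2`.
#'
#' @param errors numeric error sample.
#' @param h bandwidth.
#' @param alpha confidence level in (0, 1).
#' @return `c(l, u)`, the lower and upper error quantiles.
#' @export
error_quantiles <- function(errors, h, alpha) {
  assert_prob(alpha, "alpha")
  probs <- c((1 - alpha) / 2, (1 + alpha) / 2)
  vapply(probs, function(p) kde_quantile(errors, h, p), numeric(1))
}

kde_quantile <- function(errors, h, p, tol = 1e-8) {
  lo <- min(errors) - 12 * h
  hi <- max(errors) + 12 * h
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (kde_cdf(errors, h, mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Shift point predictions into prediction intervals
#'
#' For each confidence level the per-horizon-step error quantiles
#' `(l_alpha, u_alpha)` are added to the point predictions:
#' `lower = point + l_alpha`, `upper = point + u_alpha`. Interval width at
#' a given step is therefore constant across samples, and intervals nest
#' across increasing confidence levels.
#'
#' @param forecast a `forecast_result` for the split being bounded
#'   (typically test).
#' @param dist a fitted `error_distribution` (see [fit_error_kde()]).
#' @param alphas confidence levels, default `c(0.85, 0.90, 0.95)`.
#' @return an object of class `interval_result`: `$levels`, `$bounds`
#'   (per level: `lower`/`upper` matrices `n x tau`), `$offsets` (per
#'   level: `l`/`u` per horizon step), `$bandwidths`.
#' @export
build_intervals <- function(forecast, dist, alphas = c(0.85, 0.90, 0.95)) {
  stopifnot(inherits(forecast, "forecast_result"),
            inherits(dist, "error_distribution"))
  if (is.null(dist$bandwidths)) dist <- fit_error_kde(dist)
  tau <- ncol(forecast$point_predictions)
  step_of <- function(j) if (dist$pooled) 1L else j
  if (!dist$pooled && length(dist$errors) != tau) {
    stop_config("error distribution has %d steps but forecast has %d",
                length(dist$errors), tau)
  }
  bounds <- list(); offsets <- list()
  for (a in alphas) {
    qs <- vapply(seq_len(tau), function(j) {
      s <- step_of(j)
      error_quantiles(dist$errors[[s]], dist$bandwidths[[s]], a)
    }, numeric(2))
    lower <- sweep(forecast$point_predictions, 2, qs[1, ], "+")
    upper <- sweep(forecast$point_predictions, 2, qs[2, ], "+")
    key <- format_alpha(a)
    bounds[[key]] <- list(lower = lower, upper = upper)
    offsets[[key]] <- list(l = qs[1, ], u = qs[2, ])
  }
  structure(list(levels = alphas, bounds = bounds, offsets = offsets,
                 bandwidths = dist$bandwidths),
            class = "interval_result")
}
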