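# Point metrics (RMSE, MAE, R2), interval metrics (PICP, PINAW), and the
# relative-improvement arithmetic used in multi-model report tables.

check_pair <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop_config("metric inputs must be finite")
  }
}

#' Point-forecast error metrics
#'
#' `rmse` is the root mean squared error, `mae` the mean absolute error,
#' and `r2` the coefficient of determination
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param actual,predicted equal-length finite numeric vectors.
#' @return a scalar; `r2` is `NA` (with a warning) when the actuals have
#'   zero variance.
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname rmse
#' @export
mae <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname rmse
#' @export
r2 <- function(actual, predicted) {
  check_pair(actual, predicted)
  stopifnot(length(actual) >= 2)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    warning("R2 undefined: actuals have zero variance", call. = FALSE)
    return(NA_real_)
  }
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Prediction interval coverage probability
#'
#' Fraction of observations inside their interval; bounds count as covered
#' (closed interval).
#'
#' @param actual observations.
#' @param lower,upper interval bounds, `lower <= upper` elementwise.
#' @return coverage in `[0, 1]`.
#' @export
picp <- function(actual, lower, upper) {
  stopifnot(length(actual) == length(lower), length(lower) == length(upper))
  if (any(lower > upper)) stop_config("lower bound exceeds upper bound")
  mean(actual >= lower & actual <= upper)
}

#' Prediction interval normalized averaged width
#'
#' Mean interval width divided by the range of the observed values of the
#' evaluated set.
#'
#' @inheritParams picp
#' @return non-negative scalar.
#' @export
pinaw <- function(actual, lower, upper) {
  stopifnot(length(actual) == length(lower), length(lower) == length(upper))
  rng <- max(actual) - min(actual)
  if (rng <= 0) stop_config("degenerate observed range: max(actual) == min(actual)")
  mean(upper - lower) / rng
}

#' Relative improvement of a model over baselines, in percent
#'
#' Default (`mode = "mean"`) compares against the mean of the baselines:
#' `100 * (mean(b) - target) / mean(b)` when lower is better,
#' `100 * (target - mean(b)) / mean(b)` when higher is better.
#' `mode = "pairwise"` returns one percentage per baseline.
#'
#' @param target the model's metric value.
#' @param baselines numeric vector of baseline metric values.
#' @param direction `"lower_better"` (errors) or `"higher_better"` (R2).
#' @param mode `"mean"` or `"pairwise"`.
#' @return percentage(s), not rounded.
#' @export
relative_improvement <- function(target, baselines,
                                 direction = c("lower_better", "higher_better"),
                                 mode = c("mean", "pairwise")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (!length(baselines)) stop_config("baselines must be non-empty")
  ref <- if (mode == "mean") mean(baselines) else baselines
  if (any(ref == 0)) stop_config("baseline value of zero: improvement undefined")
  if (direction == "lower_better") 100 * (ref - target) / ref
  else 100 * (target - ref) / ref
}

#' Assemble a metric report for point and interval forecasts
#'
#' @param forecast a `forecast_result` (see [predict_convformer()]).
#' @param intervals optionally an `interval_result` (see
#'   [build_intervals()]).
#' @return a list with `point` (mae, rmse, r2 over all horizon steps and
#'   per step) and, when intervals are given, `interval` (picp, pinaw per
#'   confidence level).
#' @export
metric_report <- function(forecast, intervals = NULL) {
  act <- as.vector(forecast$actuals)
  pred <- as.vector(forecast$point_predictions)
  per_step <- data.frame(
    step = seq_len(ncol(forecast$actuals)),
    mae = vapply(seq_len(ncol(forecast$actuals)), function(j)
      mae(forecast$actuals[, j], forecast$point_predictions[, j]), 0),
    rmse = vapply(seq_len(ncol(forecast$actuals)), function(j)
      rmse(forecast$actuals[, j], forecast$point_predictions[, j]), 0))
  out <- list(point = list(mae = mae(act, pred), rmse = rmse(act, pred),
                           r2 = r2(act, pred), per_step = per_step))
  if (!is.null(intervals)) {
    out$interval <- lapply(intervals$levels, function(a) {
      key <- format_alpha(a)
      lw <- intervals$bounds[[key]]
      list(alpha = a,
           picp = picp(act, as.vector(lw$lower), as.vector(lw$upper)),
           pinaw = pinaw(act, as.vector(lw$lower), as.vector(lw$upper)))
    })
    names(out$interval) <- vapply(intervals$levels, format_alpha, "")
  }
  out
}

format_alpha <- function(a) sprintf("a%02d", round(100 * a))
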