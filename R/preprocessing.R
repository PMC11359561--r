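# Gap-aware preprocessing of a single-station multivariate hourly series:
# classify missing runs (short <= 4 h, medium 5-72 h, long > 72 h), forward
# fill short runs, average m stochastic regression imputations for medium
# runs, delete rows covered by long runs (recording segment boundaries so
# windows never span them), then min-max scale on training rows and window
# into direct multi-output (input, target) pairs.

#' Construct a single-station multivariate series
#'
#' @param timestamps POSIXct vector, strictly increasing, hourly.
#' @param values `T x M` numeric matrix, target variable (PM2.5) first.
#' @param mask logical `T x M`, `TRUE` = missing; derived from `NA`s in
#'   `values` when omitted.
#' @param feature_names column names; taken from `values` when omitted.
#' @return an object of class `series_panel`.
#' @export
series_panel <- function(timestamps, values, mask = NULL,
                         feature_names = NULL) {
  values <- as.matrix(values)
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) {
    feature_names <- sprintf("V%d", seq_len(ncol(values)))
  }
  colnames(values) <- feature_names
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask); colnames(mask) <- feature_names
  stopifnot(nrow(values) == length(timestamps),
            all(dim(mask) == dim(values)))
  if (length(timestamps) > 1) {
    dt <- diff(as.numeric(timestamps))
    if (any(dt != 3600)) {
      stop_config("timestamps must form a strict 1 h grid")
    }
  }
  structure(list(timestamps = timestamps, values = values, mask = mask,
                 feature_names = feature_names,
                 segments = data.frame(start = 1L, end = nrow(values))),
            class = "series_panel")
}

GAP_SHORT_MAX <- 4L    # forward fill up to here
GAP_MEDIUM_MAX <- 72L  # stochastic imputation up to here (72 inclusive), delete beyond

#' Classify maximal missing runs per variable
#'
#' A run of `L` consecutive missing hours is `short` when `L <= 4`,
#' `medium` when `4 < L <= 72`, and `long` when `L > 72`.
#'
#' @param x a `series_panel` or a logical matrix (`TRUE` = missing).
#' @return data frame with columns variable, start, length, class;
#'   zero rows for a fully observed series.
#' @export
classify_gaps <- function(x) {
  mask <- if (inherits(x, "series_panel")) x$mask else as.matrix(x)
  out <- list()
  for (v in seq_len(ncol(mask))) {
    r <- rle(as.logical(mask[, v]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    miss <- which(r$values)
    for (m in miss) {
      len <- r$lengths[m]
      out[[length(out) + 1L]] <- data.frame(
        variable = colnames(mask)[v] %||% sprintf("V%d", v),
        start = starts[m], length = len,
        class = if (len <= GAP_SHORT_MAX) "short"
                else if (len <= GAP_MEDIUM_MAX) "medium" else "long",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(variable = character(0), start = integer(0),
                      length = integer(0), class = character(0)))
  }
  do.call(rbind, out)
}

#' Fill or delete missing runs according to their duration class
#'
#' Short runs are forward-filled from the last observation (backward fill
#' with a log message when the series starts missing). Medium runs are
#' filled by averaging `m` stochastic regression imputations: values are
#' initialized by linear interpolation, each gap variable is regressed on
#' the other variables over originally observed rows, and each draw adds
#' residual-scaled Gaussian noise (chained-equations style, seeded).
#' Setting `method = "linear"` falls back to plain linear interpolation.
#' Rows covered by a long run in any variable are deleted and the segment
#' boundaries recorded so that later windowing never spans them.
#'
#' @param panel a `series_panel`.
#' @param method `"mice"` (default) or `"linear"` for medium runs.
#' @param m number of stochastic imputations averaged (default 5).
#' @param seed integer seed for the stochastic draws.
#' @return a `series_panel` with no missing values, a cleared mask, and a
#'   `$segments` data frame (`start`, `end` row indices of the retained,
#'   contiguous chunks in the output ordering).
#' @export
fill_gaps <- function(panel, method = c("mice", "linear"), m = 5L,
                      seed = 1L) {
  stopifnot(inherits(panel, "series_panel"))
  method <- match.arg(method)
  gaps <- classify_gaps(panel)
  vals <- panel$values
  T_ <- nrow(vals)

  # short: forward fill
  for (g in which(gaps$class == "short")) {
    v <- match(gaps$variable[g], colnames(vals))
    idx <- gaps$start[g]:(gaps$start[g] + gaps$length[g] - 1L)
    if (gaps$start[g] == 1L) {
      nxt <- gaps$start[g] + gaps$length[g]
      cf_log("info", "gap at series start in %s: backward filling",
             gaps$variable[g])
      vals[idx, v] <- vals[nxt, v]
    } else {
      vals[idx, v] <- vals[gaps$start[g] - 1L, v]
    }
  }

  # medium: averaged stochastic regression imputations
  med <- gaps[gaps$class == "medium", , drop = FALSE]
  if (nrow(med)) {
    set.seed(derive_seed(seed, 21L))
    base <- apply(vals, 2, function(col) {
      if (anyNA(col)) stats::approx(seq_along(col), col, seq_along(col),
                                    rule = 2)$y else col
    })
    for (g in seq_len(nrow(med))) {
      v <- match(med$variable[g], colnames(vals))
      idx <- med$start[g]:(med$start[g] + med$length[g] - 1L)
      if (method == "linear" || ncol(vals) < 2L) {
        vals[idx, v] <- base[idx, v]
        next
      }
      obs <- which(!panel$mask[, v])
      X <- base[, -v, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), vals[obs, v])
      sigma <- sqrt(sum(fit$residuals^2) /
                      max(1, length(obs) - ncol(X) - 1))
      pred <- cbind(1, X[idx, , drop = FALSE]) %*% fit$coefficients
      draws <- replicate(m, pred + stats::rnorm(length(idx), 0, sigma))
      vals[idx, v] <- rowMeans(matrix(draws, nrow = length(idx)))
    }
  }

  # long: delete affected rows, record segment boundaries
  drop_rows <- integer(0)
  for (g in which(gaps$class == "long")) {
    drop_rows <- union(drop_rows,
                       gaps$start[g]:(gaps$start[g] + gaps$length[g] - 1L))
  }
  keep <- setdiff(seq_len(T_), sort(drop_rows))
  vals <- vals[keep, , drop = FALSE]
  br <- which(diff(keep) > 1L)
  segments <- data.frame(start = c(1L, br + 1L),
                         end = c(br, length(keep)))
  out <- panel
  out$values <- vals
  out$timestamps <- panel$timestamps[keep]
  out$mask <- matrix(FALSE, nrow(vals), ncol(vals),
                     dimnames = dimnames(vals))
  out$segments <- segments
  if (anyNA(vals)) stop("internal error: missing values remain after fill_gaps")
  out
}

#' Fit a per-feature min-max scaler on training rows
#'
#' @param values `T x M` matrix.
#' @param rows row indices to fit on (training rows only, to avoid
#'   leaking the validation/test range).
#' @return an object of class `minmax_scaler` (per-feature min and max).
#' @export
fit_scaler <- function(values, rows = seq_len(nrow(values))) {
  values <- as.matrix(values)
  mins <- apply(values[rows, , drop = FALSE], 2, min)
  maxs <- apply(values[rows, , drop = FALSE], 2, max)
  degenerate <- which(maxs == mins)
  if (length(degenerate)) {
    stop_config("cannot scale constant feature(s): %s",
                paste(colnames(values)[degenerate], collapse = ", "))
  }
  structure(list(min = mins, max = maxs,
                 feature_names = colnames(values)), class = "minmax_scaler")
}

#' Apply / invert a min-max scaler
#'
#' `apply_scaler` maps training rows into `[0, 1]`; values outside the
#' training range (possible on validation/test rows) map outside and are
#' logged. `invert_scaler` restores original units; `feature` restricts
#' inversion to one feature's column(s).
#'
#' @param x matrix (or vector) of values.
#' @param scaler a `minmax_scaler`.
#' @param feature optional feature name (for inverting target columns).
#' @return matrix (or vector) of the same shape.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x <- as.matrix(x)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2,
               scaler$max - scaler$min, "/")
  n_out <- sum(out < 0 | out > 1)
  if (n_out > 0) {
    cf_log("debug", "%d scaled values fall outside (0, 1)", n_out)
  }
  out
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(x, scaler, feature = NULL) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (!is.null(feature)) {
    i <- match(feature, scaler$feature_names)
    if (is.na(i)) stop_config("unknown feature '%s'", feature)
    return(x * (scaler$max[i] - scaler$min[i]) + scaler$min[i])
  }
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")
}

#' Chronological 7:1:2 split and direct multi-output windowing
#'
#' Rows (after gap handling) are split chronologically into train /
#' validation / test by the given ratios. Within each retained segment,
#' every index `t` with `D` history rows and `tau` future rows inside the
#' segment yields one window: inputs are rows `t-D+1 .. t` over all
#' features, the target is the PM2.5 column at rows `t+1 .. t+tau`. A
#' window belongs to the split of its input end `t` (targets may look past
#' a split boundary but never past a deleted-segment boundary). The scaler
#' is fitted on training rows only and applied everywhere.
#'
#' @param panel a gap-free `series_panel` (from [fill_gaps()]).
#' @param D input window length (rows).
#' @param tau forecast horizon (rows), typically 24, 48, or 96.
#' @param ratios length-3 positive weights, default `c(7, 1, 2)`.
#' @param target target feature name, default the first column.
#' @return an object of class `windowed_dataset`: `$values` (scaled
#'   `T x M`), `$index` (data frame `t`, `segment`, `split`), `$scaler`,
#'   `$D`, `$tau`, `$target`, `$row_split`.
#' @export
split_and_window <- function(panel, D, tau, ratios = c(7, 1, 2),
                             target = NULL) {
  stopifnot(inherits(panel, "series_panel"))
  assert_count(D, "D"); assert_count(tau, "tau")
  if (any(panel$mask)) stop_config("panel still has missing values; run fill_gaps() first")
  if (length(ratios) != 3L || any(ratios <= 0)) {
    stop_config("ratios must be three positive numbers")
  }
  target <- target %||% panel$feature_names[1]
  ti <- match(target, panel$feature_names)
  if (is.na(ti)) stop_config("target feature '%s' not in panel", target)
  T_ <- nrow(panel$values)
  n_train <- floor(T_ * ratios[1] / sum(ratios))
  n_val <- floor(T_ * (ratios[1] + ratios[2]) / sum(ratios)) - n_train
  row_split <- rep("test", T_)
  row_split[seq_len(n_train)] <- "train"
  if (n_val > 0) row_split[n_train + seq_len(n_val)] <- "val"

  idx <- list()
  for (s in seq_len(nrow(panel$segments))) {
    a <- panel$segments$start[s]; b <- panel$segments$end[s]
    if (b - a + 1L < D + tau) {
      cf_log("info", "segment %d (%d rows) shorter than D + tau = %d: no windows",
             s, b - a + 1L, D + tau)
      next
    }
    t_range <- seq.int(a + D - 1L, b - tau)
    idx[[length(idx) + 1L]] <- data.frame(t = t_range, segment = s,
                                          split = row_split[t_range],
                                          stringsAsFactors = FALSE)
  }
  index <- if (length(idx)) do.call(rbind, idx) else
    data.frame(t = integer(0), segment = integer(0), split = character(0))

  scaler <- fit_scaler(panel$values, rows = which(row_split == "train"))
  structure(list(values = apply_scaler(panel$values, scaler),
                 raw_values = panel$values,
                 index = index, scaler = scaler, D = as.integer(D),
                 tau = as.integer(tau), target = target,
                 target_col = ti, row_split = row_split,
                 feature_names = panel$feature_names),
            class = "windowed_dataset")
}

#' Materialize windows of a split as arrays
#'
#' @param wd a `windowed_dataset`.
#' @param split `"train"`, `"val"`, or `"test"`.
#' @param indices optional subset (row numbers of `wd$index` within the
#'   split) to materialize.
#' @return list with `inputs` (`n x D x M`) and `targets` (`n x tau`),
#'   both in scaled units, plus the window end rows `t`.
#' @export
get_windows <- function(wd, split = "train", indices = NULL) {
  stopifnot(inherits(wd, "windowed_dataset"))
  sel <- wd$index[wd$index$split == split, , drop = FALSE]
  if (!is.null(indices)) sel <- sel[indices, , drop = FALSE]
  n <- nrow(sel)
  M <- ncol(wd$values)
  inputs <- array(0, dim = c(n, wd$D, M))
  targets <- matrix(0, n, wd$tau)
  for (i in seq_len(n)) {
    t <- sel$t[i]
    inputs[i, , ] <- wd$values[(t - wd$D + 1L):t, , drop = FALSE]
    targets[i, ] <- wd$values[(t + 1L):(t + wd$tau), wd$target_col]
  }
  list(inputs = inputs, targets = targets, t = sel$t)
}
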