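# Pearson screening of candidate features against target-station PM2.5.

#' Pairwise-complete Pearson correlation matrix of a panel
#'
#' @param panel a `series_panel`, or a numeric matrix with named columns
#'   (missing values allowed).
#' @return an object of class `correlation_report`: `$pairs` (symmetric
#'   correlation matrix with unit diagonal), `$constant` (names of
#'   zero-variance features, whose correlations are undefined).
#' @export
pearson_matrix <- function(panel) {
  vals <- if (inherits(panel, "series_panel")) {
    v <- panel$values; v[panel$mask] <- NA; v
  } else as.matrix(panel)
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(vals)[!is.na(sds) & sds == 0]
  suppressWarnings(
    r <- stats::cor(vals, use = "pairwise.complete.obs")
  )
  diag(r) <- 1
  structure(list(pairs = r, constant = constant),
            class = "correlation_report")
}

#' Screen features by absolute correlation with the target
#'
#' Features whose `|r|` with the target falls below `r_min` are dropped
#' (the target itself is always kept); the boundary `|r| == r_min` keeps
#' the feature. Zero-variance features are dropped with reason
#' `"zero variance"`. Screening is idempotent: re-running on the kept set
#' changes nothing.
#'
#' @param report a `correlation_report` from [pearson_matrix()].
#' @param target target feature name (e.g. `"PM2.5"`).
#' @param r_min absolute-correlation threshold, default 0.1.
#' @return list with `kept` (character), `dropped` (data frame feature,
#'   reason), and `r_target` (named correlations with the target).
#' @export
screen_features <- function(report, target = "PM2.5", r_min = 0.1) {
  stopifnot(inherits(report, "correlation_report"))
  feats <- colnames(report$pairs)
  if (!target %in% feats) stop_config("target '%s' not among features", target)
  r_target <- report$pairs[, target]
  kept <- character(0)
  dropped <- data.frame(feature = character(0), reason = character(0))
  for (f in feats) {
    if (f == target) { kept <- c(kept, f); next }
    if (f %in% report$constant || is.na(r_target[[f]])) {
      dropped <- rbind(dropped,
                       data.frame(feature = f, reason = "zero variance"))
    } else if (abs(r_target[[f]]) < r_min) {
      dropped <- rbind(dropped, data.frame(
        feature = f, reason = sprintf("|r| = %.4f < %.3f",
                                      abs(r_target[[f]]), r_min)))
    } else {
      kept <- c(kept, f)
    }
  }
  list(kept = kept, dropped = dropped, r_target = r_target)
}

#' Drop screened-out columns from a series panel
#'
#' @param panel a `series_panel`.
#' @param kept character vector of features to keep (target first).
#' @return the reduced `series_panel`.
#' @export
keep_features <- function(panel, kept) {
  stopifnot(inherits(panel, "series_panel"))
  idx <- match(kept, panel$feature_names)
  if (anyNA(idx)) stop_config("unknown feature(s): %s",
                              paste(kept[is.na(idx)], collapse = ", "))
  panel$values <- panel$values[, idx, drop = FALSE]
  panel$mask <- panel$mask[, idx, drop = FALSE]
  panel$feature_names <- kept
  panel
}
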