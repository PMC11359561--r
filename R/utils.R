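#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed. Each stage uses
#' `root * 97 + offset` reduced modulo 2^31 - 1 so that stages are decoupled
#' (changing the model seed does not perturb the data seed) while the whole
#' run remains reproducible from a single integer.
#'
#' @param root integer root seed.
#' @param offset integer stage offset (each stage has a fixed one).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, offset = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  as.integer((abs(root) * 97 + offset) %% (2^31 - 1))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop_config("'%s' must be an integer >= %d (got %s)", name, min,
                paste(format(x), collapse = ","))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop_config("'%s' must lie in %s (got %s)", name,
                       if (open) "(0, 1)" else "[0, 1]", format(x))
  invisible(x)
}

# message() wrapper honouring the package-level log level
cf_log <- function(level = c("info", "warn", "debug"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("convformer.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[threshold]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
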