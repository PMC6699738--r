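#' @keywords internal
"_PACKAGE"

expit <- function(x) 1 / (1 + exp(-x))

#' Derive a named random substream seed
#'
#' Expands a single integer master seed into independent named substreams so
#' that adding a downstream stage never perturbs the draws of an earlier one.
#' The derived seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (for example, `"genotypes"`).
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) * 69069 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stop_if_not_prob <- function(x, what) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

## two-sided P from a z statistic, guarded against 0 underflow in logs
z_to_p <- function(z) 2 * stats::pnorm(abs(z), lower.tail = FALSE)
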