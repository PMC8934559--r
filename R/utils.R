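# Internal helpers shared across modules.

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic operations in the package funnel their seed through this
#' helper so that every generator output is a pure function of
#' (arguments, seed) and never perturbs the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed and a stream index; keeps all
# derived seeds in the 31-bit signed range.
derive_seed <- function(master_seed, index) {
  master_seed <- as.double(master_seed)
  index <- as.double(index)
  as.integer((master_seed * 48271 + index * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population moments with the degenerate-plane convention: a zero-variance
# sample has skewness 0 and excess kurtosis 0.
moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= .Machine$double.eps) {
    c(mean = m, var = 0, skew = 0, kurt = 0)
  } else {
    s <- mean((x - m)^3) / v^1.5
    k <- mean((x - m)^4) / v^2 - 3
    c(mean = m, var = v, skew = s, kurt = k)
  }
}

# Pearson correlation that fails loudly on zero-variance input instead of
# returning NA.
pearson_strict <- function(x, y, what = "input") {
  if (length(x) != length(y)) {
    stop("pearson_strict: length mismatch", call. = FALSE)
  }
  if (length(x) < 3L) stop("pearson_strict: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(sprintf("zero-variance %s in correlation", what), call. = FALSE)
  }
  stats::cor(x, y)
}
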