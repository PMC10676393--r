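# Internal helpers shared across modules.

#' @importFrom stats plogis qlogis rbinom rnorm runif uniroot var cor coef
#'   sd quantile pchisq glm glm.fit binomial predict complete.cases
#'   setNames simulate residuals aggregate
#' @importFrom graphics matplot abline legend
NULL

# Deterministic sub-stream seed derived from a master seed and a stage name,
# kept below 2^31 so it is a valid R integer seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 104729L
  as.integer((as.numeric(seed) * 7919 + h * 31 + 17) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  withr::with_seed(substream_seed(seed, name), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# z-standardize, returning zeros when the spread is degenerate
zstd <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
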