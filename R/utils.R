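#' @importFrom stats runif rnorm rgeom setNames
#' @importFrom utils modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL means "use the ambient RNG state".
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == trunc(x) && x >= min
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# round-half-up, used wherever pixel dimensions are derived from scale factors
round_half_up <- function(x) floor(x + 0.5)
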