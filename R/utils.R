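#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All generator functions route their randomness through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

assert_positive <- function(x, name) {
  if (!all(is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(x)
}

# Resolve a distribution argument: a function(n) -> numeric, a single
# number (constant), or a numeric vector (sampled with replacement).
as_sampler <- function(spec, name) {
  if (is.function(spec)) return(spec)
  if (is.numeric(spec) && length(spec) == 1L)
    return(function(n) rep(spec, n))
  if (is.numeric(spec))
    return(function(n) sample(spec, n, replace = TRUE))
  stop(sprintf("'%s' must be a function(n) or numeric", name), call. = FALSE)
}
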