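#' @importFrom rlang abort warn .data `%||%`
#' @importFrom stats plogis rnorm approx lm coef predict sd var cor optim
#' @importFrom stats resid
#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG state seeded by `seed`; the caller's RNG stream is
# untouched. seed = NULL runs expr with the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based derivation so that each protocol bin, training
#' restart or closed-loop trial gets an independent, reproducible RNG stream
#' from one master seed. Always returns a positive integer below 2^31 - 1.
#'
#' @param seed Master seed (integer).
#' @param index Nonnegative counter (bin index, restart index, ...).
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index), index >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime: full-period Lehmer modulus
  s <- (abs(as.numeric(seed)) %% m)
  x <- (s * 48271 + (as.numeric(index) + 1) * 16807) %% m
  # one multiplicative mixing round so adjacent indices decorrelate
  x <- (x * 69621) %% m
  as.integer(x + 1)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s] (got %s).", name, lower, upper, x))
  }
  invisible(x)
}
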