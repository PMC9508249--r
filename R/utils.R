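# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import Rcpp
#' @useDynLib memcortex, .registration = TRUE
NULL

# Deterministic child-seed derivation: one root seed fans out to per-component
# streams.  Multiplier kept small so root * 69069 stays exactly representable
# in a double; result is always a valid 31-bit integer seed.
child_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.numeric(index))
  as.integer((abs(root) * 69069 + index * 7919) %% 2147483629)
}

# Run `expr` under a local RNG state seeded with `seed`; if `seed` is NULL the
# global RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be a single number, not NULL.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower) {
    if (x <= lower) abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  } else if (x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  invisible(x)
}
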