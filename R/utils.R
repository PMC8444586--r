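#' Derive a stream of child seeds from a master seed
#'
#' Every stochastic step in the package draws its own integer seed from a
#' master seed through this helper, so that independent stages (subsampling,
#' splitting, forest training, noise generation) are decoupled: changing the
#' number of draws in one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483645L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper), call. = FALSE)
  }
  invisible(x)
}
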