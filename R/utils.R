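`%||%` <- function(a, b) if (is.null(a)) b else a

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

#' Derive a stream of child seeds from one master seed
#'
#' All stochastic stages consume seeds drawn from this helper so that a single
#' integer reproduces an entire analysis. Seeds stay below `2^31 - 1`.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(.is_count(n))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
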