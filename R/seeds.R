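#' Deterministic seed streams
#'
#' Every stochastic step (undersampling, outer split, k-means, inner scoring
#' splits, learner fits) draws its own seed derived from the master seed and
#' the integer context of the step (repetition, iteration, cluster, split).
#' The derivation is a fixed multiplicative-congruential fold modulo
#' 2^31 - 1, so two runs with the same master seed are bit-identical while
#' neighbouring contexts are decorrelated. All derived seeds stay below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Further non-negative integers identifying the context.
#' @return A single integer in \[1, 2^31 - 2\].
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(master, ...) {
  ctx <- c(master, ...)
  m <- 2147483647 # 2^31 - 1, prime
  x <- 987654321
  for (k in ctx) {
    # 69069 * 2^31 < 2^53: exact in double arithmetic
    x <- (x * 69069 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(x + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
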