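#' Simulate a two-class matrix with planted correlated feature blocks
#'
#' Generates the kind of samples-by-features table the engine consumes, with
#' known ground truth: a handful of "planted" blocks of mutually correlated
#' informative features on top of independent Gaussian noise. Each block is
#' drawn from an equicorrelated multivariate normal (pairwise correlation
#' `rho`, built as a shared factor plus independent residuals) and carries a
#' between-class mean shift of `effect` within-class standard deviations, so
#' standardized k-means groups the block together and the shift is what a
#' two-sample t-test measures. Remaining features are independent
#' `N(0, noise_sd^2)` noise in both classes.
#'
#' @param n_pos,n_neg Samples per class; unequal counts exercise
#'   undersampling.
#' @param n_features Total feature count (planted + noise).
#' @param blocks Data frame with one row per planted block and columns
#'   `size` (features in the block), `effect` (mean shift in SD units,
#'   >= 0) and `rho` (within-block equicorrelation in \[0, 1)).
#' @param noise_sd Within-class standard deviation of every feature.
#' @param seed Integer seed; generation is fully deterministic given the
#'   arguments.
#' @return A list with `data` (labeled tibble, planted features named
#'   `block<i>_f<j>`, noise features `noise<k>`) and `informative`
#'   (character vector of planted feature ids).
#' @export
#' @examples
#' sim <- simulate_blocks(n_pos = 20, n_neg = 20, n_features = 50,
#'                        blocks = data.frame(size = 5, effect = 2, rho = 0.8),
#'                        seed = 1)
#' dim(sim$data)
simulate_blocks <- function(n_pos, n_neg, n_features,
                            blocks = data.frame(size = integer(), effect = numeric(),
                                                rho = numeric()),
                            noise_sd = 1, seed = 1L) {
  blocks <- as.data.frame(blocks)
  stopifnot(n_pos >= 1, n_neg >= 1, n_features >= 1, noise_sd > 0)
  if (nrow(blocks)) {
    if (!all(c("size", "effect", "rho") %in% names(blocks))) {
      abort("`blocks` needs columns size, effect, rho.", class = "rceife_parameter_error")
    }
    if (any(blocks$effect < 0) || any(blocks$rho < 0 | blocks$rho >= 1)) {
      abort("block effects must be >= 0 and rho in [0, 1).", class = "rceife_parameter_error")
    }
  }
  n_planted <- sum(blocks$size)
  if (n_planted > n_features) {
    abort("sum of block sizes exceeds n_features.", class = "rceife_parameter_error")
  }
  n <- n_pos + n_neg
  labels <- rep(c("pos", "neg"), c(n_pos, n_neg))
  with_seed(seed, {
    cols <- vector("list", nrow(blocks) + 1L)
    ids <- character(0)
    for (b in seq_len(nrow(blocks))) {
      s <- blocks$size[b]
      rho <- blocks$rho[b]
      # equicorrelated gaussian: shared factor + residual, unit marginal variance
      shared <- rnorm(n)
      x <- sqrt(rho) * matrix(shared, n, s) +
        sqrt(1 - rho) * matrix(rnorm(n * s), n, s)
      x <- x * noise_sd
      x[labels == "pos", ] <- x[labels == "pos", ] + blocks$effect[b] * noise_sd
      cols[[b]] <- x
      ids <- c(ids, sprintf("block%d_f%02d", b, seq_len(s)))
    }
    n_noise <- n_features - n_planted
    if (n_noise > 0) {
      cols[[nrow(blocks) + 1L]] <- matrix(rnorm(n * n_noise, sd = noise_sd), n, n_noise)
      ids <- c(ids, sprintf("noise%04d", seq_len(n_noise)))
    }
    m <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
    colnames(m) <- ids
    data <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      label = labels
    )
    data <- dplyr::bind_cols(data, tibble::as_tibble(m))
    list(
      data = as_labeled_data(data),
      informative = ids[seq_len(n_planted)]
    )
  })
}

#' Ground-truth partition of planted blocks
#'
#' Companion to [simulate_blocks()]: the block index of each planted feature,
#' for comparing a recovered clustering against the generating partition.
#'
#' @param informative The `informative` vector returned by [simulate_blocks()].
#' @return Integer vector of block indices, named by feature id.
#' @export
planted_partition <- function(informative) {
  idx <- as.integer(sub("^block(\\d+)_f\\d+$", "\\1", informative))
  names(idx) <- informative
  idx
}
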