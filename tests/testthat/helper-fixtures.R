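# Small fixtures built in code; everything is deterministic under the seed.

# a labeled tibble with gaussian noise features and optional mean shift on
# the first `n_informative` features
toy_data <- function(n_pos = 10, n_neg = 10, n_feat = 6, shift = 0,
                     n_informative = 0, seed = 1) {
  sim <- simulate_blocks(
    n_pos = n_pos, n_neg = n_neg, n_features = n_feat,
    blocks = if (n_informative > 0) {
      data.frame(size = n_informative, effect = shift, rho = 0)
    } else {
      data.frame(size = integer(), effect = numeric(), rho = numeric())
    },
    seed = seed
  )
  sim$data
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# the strong-signal study matrix used across engine-level checks:
# 60/60 samples, 2,000 features, 3 planted blocks of 10 (effect 1.5 SD,
# rho 0.6)
strong_signal_sim <- function(seed = 3) {
  simulate_blocks(
    n_pos = 60, n_neg = 60, n_features = 2000,
    blocks = data.frame(size = c(10, 10, 10), effect = 1.5, rho = 0.6),
    seed = seed
  )
}
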