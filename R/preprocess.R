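#' Balance classes by random undersampling
#'
#' Removes randomly chosen majority-class samples until the class counts are
#' equal, keeping every minority-class sample — the standard remedy for the
#' heavy imbalance of clinical cohorts (e.g. 408 tumour vs 17 normal), where
#' a classifier trained on the raw data would otherwise score well by always
#' predicting the majority.
#'
#' @param data A labeled tibble.
#' @param seed Integer seed for the majority draw.
#' @return A labeled tibble with equal class counts, rows in original order.
#' @export
undersample <- function(data, seed = 1L) {
  data <- as_labeled_data(data)
  counts <- check_two_class(data, "undersample")
  n_min <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(label_levels, function(l) {
      idx <- which(data$label == l)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  data[sort(keep), ]
}

#' Stratified train/test split
#'
#' Randomly assigns, per class, `floor(train_fraction * class_count)` samples
#' to the training side and the rest to the test side, so both sides keep
#' both classes (a test side that would come out empty for a class gets one
#' sample moved back from train). Stratification guarantees test-set AUC is
#' always defined.
#'
#' @param data A labeled tibble; each class needs >= 2 samples.
#' @param train_fraction Fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return A list with labeled tibbles `train` and `test`.
#' @export
stratified_split <- function(data, train_fraction = 0.9, seed = 1L) {
  data <- as_labeled_data(data)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie strictly in (0, 1).", class = "rceife_split_error")
  }
  counts <- check_two_class(data, "stratified_split")
  if (any(counts < 2L)) {
    abort("each class needs at least 2 samples to split.", class = "rceife_split_error")
  }
  train_idx <- stratified_train_idx(data$label, train_fraction, seed)
  list(
    train = data[train_idx, ],
    test = data[setdiff(seq_len(nrow(data)), train_idx), ]
  )
}

# the one stratified assignment rule, shared by the outer split and the
# inner scoring splits: per class floor(fraction * count) to train, with an
# empty-test guard; returns sorted train row indices
stratified_train_idx <- function(labels, train_fraction, seed) {
  idx <- with_seed(seed, {
    unlist(lapply(label_levels, function(l) {
      cls <- which(labels == l)
      n_train <- floor(train_fraction * length(cls))
      if (n_train >= length(cls)) n_train <- length(cls) - 1L # empty-test guard
      if (n_train < 1L) n_train <- 1L
      sample(cls, n_train)
    }))
  })
  sort(idx)
}

#' Univariate t-test pre-filter
#'
#' Ranks every feature by a two-sided two-sample t-test between the classes
#' on the training data and returns the `n_top` smallest p-values — the
#' coarse screen that cuts tens of thousands of features down to a set the
#' iterative engine can cluster. Welch's unequal-variance statistic is the
#' default; the pooled-variance variant is available. Features constant in
#' both classes get p = 1 so they sort last; ties keep original column order.
#'
#' @param train A labeled tibble; each class needs >= 2 samples.
#' @param n_top Number of features to keep (default 1000); capped at the
#'   feature count.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return Character vector of feature ids, ascending p-value.
#' @export
ttest_filter <- function(train, n_top = 1000L, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  train <- as_labeled_data(train)
  counts <- check_two_class(train, "ttest_filter")
  if (any(counts < 2L)) {
    abort("each class needs at least 2 samples for the t-test.",
          class = "rceife_statistics_error")
  }
  p <- ttest_pvalues(train, variant)
  ord <- order(p) # ties keep column order (order() is stable)
  feats <- feature_ids(train)
  feats[head(ord, min(n_top, length(feats)))]
}

# vectorized two-sided two-sample t-test p-values over all feature columns
ttest_pvalues <- function(train, variant = "welch") {
  m <- feature_matrix(train)
  pos <- m[train$label == "pos", , drop = FALSE]
  neg <- m[train$label == "neg", , drop = FALSE]
  n1 <- nrow(pos); n2 <- nrow(neg)
  m1 <- colMeans(pos); m2 <- colMeans(neg)
  v1 <- colSums((pos - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((neg - rep(m2, each = n2))^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  stat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  p[is.nan(stat)] <- 1      # constant in both classes, equal means
  p[is.infinite(stat)] <- 0 # zero variance but separated means
  unname(p)
}
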