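#' Group active features into clusters by k-means
#'
#' Each feature is a point in sample-space (its vector of training values),
#' z-scored per feature by default so Euclidean k-means tracks co-expression
#' shape rather than absolute scale. Correlated feature blocks then fall into
#' the same cluster, which is what makes eliminating whole clusters a
#' redundancy-aware move. Input feature order is canonicalized (sorted)
#' before clustering so the partition depends only on the feature *set*,
#' the data and the seed.
#'
#' @param train A labeled tibble (training samples).
#' @param active_features Features to cluster; must exist in `train`.
#' @param k Requested cluster count (>= 1). When `k >=` the number of active
#'   features every feature becomes a singleton. Empty clusters returned by
#'   the backend are dropped, so the effective count can be below `k`.
#' @param seed Integer seed for the k-means restarts.
#' @param standardize Z-score each feature across training samples first
#'   (default `TRUE`); zero-variance features become zero vectors.
#' @param restarts,max_iter k-means restarts (default 10) and iteration cap
#'   (default 300).
#' @return A partition tibble with columns `feature_id` and `cluster_id`
#'   (consecutive integers from 1; ids assigned in order of each cluster's
#'   first feature).
#' @export
cluster_features <- function(train, active_features, k, seed = 1L,
                             standardize = TRUE, restarts = 10L, max_iter = 300L) {
  if (k < 1L) abort("k must be >= 1.", class = "rceife_parameter_error")
  train <- as_labeled_data(train)
  active_features <- sort(unique(active_features))
  x <- t(feature_matrix(restrict_features(train, active_features)))
  if (standardize) {
    mu <- rowMeans(x)
    s <- apply(x, 1L, sd)
    s[s == 0] <- 1 # zero-variance feature -> zero vector, not NaN
    x <- (x - mu) / s
  }
  n_feat <- nrow(x)
  if (k >= n_feat) {
    assign <- seq_len(n_feat)
  } else if (k == 1L) {
    assign <- rep(1L, n_feat)
  } else {
    km <- with_seed(seed, suppressWarnings(
      kmeans(x, centers = k, nstart = restarts, iter.max = max_iter)
    ))
    assign <- km$cluster
  }
  # relabel clusters by first appearance so ids are order-canonical
  relabel <- match(assign, unique(assign))
  tibble::tibble(feature_id = rownames(x), cluster_id = relabel) |>
    dplyr::arrange(.data$cluster_id, .data$feature_id)
}

#' Restrict a dataset to one cluster's features
#'
#' The per-cluster "subdataset": the column restriction of the training table
#' to the cluster's features, labels untouched. This is what the scoring and
#' importance learners are fit on.
#'
#' @param data A labeled tibble.
#' @param features Character vector of the cluster's feature ids.
#' @return A labeled tibble with only those feature columns.
#' @export
build_subdataset <- function(data, features) {
  if (!length(features)) abort("cluster has no features.", class = "rceife_parameter_error")
  if (!all(c("sample_id", "label") %in% names(data))) {
    abort("`data` must be a labeled tibble.", class = "rceife_format_error")
  }
  restrict_features(data, features)
}

partition_features <- function(partition, id) {
  partition$feature_id[partition$cluster_id == id]
}
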