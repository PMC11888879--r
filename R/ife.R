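#' Per-feature importance weights within a cluster
#'
#' Fits the learner once on the cluster's subdataset with the full training
#' labels and returns its native importance weight for every cluster feature:
#' mean impurity decrease for the random forest, absolute linear coefficient
#' for the SVM variant. These weights drive intra-cluster pruning.
#'
#' @inheritParams score_cluster
#' @return A tibble with `feature_id` and `importance` (>= 0), one row per
#'   cluster feature.
#' @export
feature_importances <- function(cluster_features, train,
                                learner = "random_forest", seed = 1L, ntree = 100L) {
  sub <- build_subdataset(train, cluster_features)
  check_two_class(sub, "feature_importances")
  fit <- fit_learner(sub, learner, seed = seed, ntree = ntree)
  imp <- learner_importance(fit)
  tibble::tibble(feature_id = names(imp), importance = unname(imp))
}

#' Prune the lowest-importance features of a cluster
#'
#' Removes the bottom `f`% of a cluster's features by importance, but only
#' when the cluster holds more than `min_size` features — small clusters are
#' left intact so strong compact clusters keep a minimal representative set.
#' For eligible clusters the removal count is `max(1, floor(f/100 * size))`:
#' the `max(1, .)` guarantees progress for sizes where the floor alone would
#' remove nothing (6–9 features at f = 10). Importance ties at the removal
#' boundary break by feature id: among tied features the later id is removed
#' first. The result is never empty.
#'
#' @param importances A tibble with `feature_id` and `importance` covering
#'   exactly the cluster (from [feature_importances()]).
#' @param f Percentage of features to remove (default 10); `f = 0` disables
#'   pruning.
#' @param min_size Clusters of at most this many features are untouched
#'   (default 5).
#' @return The surviving rows of `importances`, original order preserved.
#' @export
eliminate_within_cluster <- function(importances, f = 10, min_size = 5L) {
  if (!all(c("feature_id", "importance") %in% names(importances))) {
    abort("`importances` needs feature_id and importance columns.",
          class = "rceife_state_error")
  }
  if (anyNA(importances$importance)) {
    abort("importances must be complete.", class = "rceife_state_error")
  }
  n <- nrow(importances)
  if (f <= 0 || n <= min_size) return(importances)
  n_remove <- max(1L, floor(f / 100 * n))
  n_remove <- min(n_remove, n - 1L) # never empty a cluster
  ord <- order(importances$importance, -xtfrm(importances$feature_id))
  drop_idx <- ord[seq_len(n_remove)]
  importances[-drop_idx, ]
}
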