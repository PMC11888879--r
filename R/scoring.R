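#' Score one cluster by repeated stratified subsampling
#'
#' The cluster's score is the mean held-out accuracy of a classifier trained
#' on only that cluster's features, over `t` independent stratified random
#' 70/30 splits of the training data (Monte-Carlo cross-validation). A
#' cluster of features that jointly discriminate the classes scores high; a
#' cluster of noise hovers near chance.
#'
#' @param cluster_features Character vector of the cluster's feature ids.
#' @param train A labeled tibble (training samples, both classes with >= 2
#'   samples each).
#' @param t Number of random 70/30 partitions (default 10).
#' @param inner_train_fraction Fraction of samples in each inner training
#'   side (default 0.7).
#' @param learner `"random_forest"` (default) or `"svm"`.
#' @param seed Integer seed; split `i` and its fit use seeds derived from
#'   `(seed, i)`.
#' @param ntree Trees per forest (default 100).
#' @return The mean accuracy, a number in \[0, 1\].
#' @export
score_cluster <- function(cluster_features, train, t = 10L,
                          inner_train_fraction = 0.7,
                          learner = "random_forest", seed = 1L, ntree = 100L) {
  if (t < 1L) abort("t must be >= 1.", class = "rceife_parameter_error")
  sub <- build_subdataset(train, cluster_features)
  check_two_class(sub, "score_cluster")
  x <- feature_matrix(sub)
  y <- sub$label
  acc <- vapply(seq_len(t), function(i) {
    idx <- stratified_train_idx(y, inner_train_fraction, seed = derive_seed(seed, i, 1L))
    model <- with_seed(derive_seed(seed, i, 2L), {
      if (learner == "random_forest") {
        randomForest::randomForest(x = x[idx, , drop = FALSE], y = y[idx], ntree = ntree)
      } else {
        e1071::svm(x = x[idx, , drop = FALSE], y = y[idx],
                   kernel = "linear", cost = 1, scale = FALSE)
      }
    })
    pred <- predict(model, x[-idx, , drop = FALSE])
    mean(as.character(pred) == as.character(y[-idx]))
  }, numeric(1))
  mean(acc)
}

#' Score every cluster of a partition
#'
#' Maps [score_cluster()] over a partition tibble, deriving one seed per
#' cluster from the partition-level seed.
#'
#' @param partition A partition tibble (`feature_id`, `cluster_id`) from
#'   [cluster_features()].
#' @param train A labeled tibble.
#' @inheritParams score_cluster
#' @return A tibble with `cluster_id`, `n_features`, `score`, one row per
#'   cluster.
#' @export
score_clusters <- function(partition, train, t = 10L, inner_train_fraction = 0.7,
                           learner = "random_forest", seed = 1L, ntree = 100L) {
  ids <- unique(partition$cluster_id)
  purrr::map_dfr(ids, function(cid) {
    feats <- partition_features(partition, cid)
    tibble::tibble(
      cluster_id = cid,
      n_features = length(feats),
      score = score_cluster(feats, train, t, inner_train_fraction, learner,
                            seed = derive_seed(seed, cid), ntree = ntree)
    )
  })
}

#' Eliminate the lowest-scoring clusters
#'
#' Keeps the `m_next` highest-scoring clusters of a scored partition and
#' drops the rest — dropping a cluster drops every feature in it. Ties at
#' the boundary are broken deterministically: clusters sort by score
#' descending then `cluster_id` ascending, so among tied clusters the
#' largest id is eliminated first.
#'
#' @param scored A tibble with `cluster_id` and `score` (from
#'   [score_clusters()]); `NA` scores are an error.
#' @param m_next Number of clusters to keep; must lie in
#'   \[1, number of clusters\].
#' @return `scored` restricted to the survivors, ordered score-descending.
#' @export
eliminate_clusters <- function(scored, m_next) {
  if (anyNA(scored$score)) abort("all clusters must be scored.", class = "rceife_state_error")
  n <- nrow(scored)
  if (m_next < 1L || m_next > n) {
    abort(paste0("m_next must lie in [1, ", n, "]."), class = "rceife_parameter_error")
  }
  scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$cluster_id) |>
    head(m_next)
}
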