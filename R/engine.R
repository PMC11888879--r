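#' One grouping / scoring / elimination / pruning / evaluation step
#'
#' The body of the main loop for one consecutive schedule pair
#' `(m_i, m_next)`: cluster the active features into `min(m_i, #active)`
#' groups, score every cluster, keep the `m_next` best, prune the weakest
#' features inside each survivor, pool the remainder into the new active set,
#' then fit the modeling learner on the feature-restricted training data and
#' evaluate the full metric set on the feature-restricted held-out test data.
#' If k-means returns fewer effective clusters than `m_next`, cluster
#' elimination is skipped for the step (with a warning) and pruning still
#' runs.
#'
#' @param train,test Labeled tibbles from the outer split.
#' @param active_features Currently active feature ids.
#' @param m_i,m_next The schedule pair; `m_i > m_next >= 1`.
#' @param config Engine configuration from [rce_ife_config()].
#' @param seed Iteration-level seed; all inner seeds derive from it.
#' @return A list with `level` (= `m_next`), `surviving_features`,
#'   `n_features`, `n_clusters` (effective survivor count) and `metrics`
#'   (one-row tibble from [classification_metrics()]).
#' @export
run_iteration <- function(train, test, active_features, m_i, m_next, config, seed = 1L) {
  if (!(m_i > m_next && m_next >= 1L)) {
    abort("need m_i > m_next >= 1.", class = "rceife_parameter_error")
  }
  if (!length(active_features)) abort("no active features.", class = "rceife_engine_error")

  partition <- cluster_features(
    train, active_features, k = min(m_i, length(active_features)),
    seed = derive_seed(seed, 1L),
    standardize = config$standardize,
    restarts = config$kmeans_restarts, max_iter = config$kmeans_max_iter
  )
  scored <- score_clusters(
    partition, train, t = config$t,
    inner_train_fraction = config$inner_train_fraction,
    learner = config$learner, seed = derive_seed(seed, 2L), ntree = config$ntree
  )
  effective <- nrow(scored)
  if (effective < m_next) {
    warn(paste0("effective cluster count ", effective, " below schedule level ",
                m_next, "; skipping cluster elimination for this step."))
    survivors <- scored
  } else {
    survivors <- eliminate_clusters(scored, m_next)
  }

  kept <- purrr::map(survivors$cluster_id, function(cid) {
    feats <- partition_features(partition, cid)
    imp <- feature_importances(feats, train, learner = config$learner,
                               seed = derive_seed(seed, 3L, cid), ntree = config$ntree)
    eliminate_within_cluster(imp, f = config$f,
                             min_size = config$min_cluster_size_for_ife)$feature_id
  })
  f_star <- sort(unique(unlist(kept)))
  if (!length(f_star)) abort("survivor pool is empty.", class = "rceife_engine_error")

  train_r <- restrict_features(train, f_star)
  test_r <- restrict_features(test, f_star)
  fit <- fit_learner(train_r, config$learner, seed = derive_seed(seed, 4L),
                     ntree = config$ntree)
  metrics <- classification_metrics(
    truth = test_r$label,
    estimate = predict_class(fit, test_r),
    scores = predict_score(fit, test_r)
  )
  list(
    level = m_next,
    surviving_features = f_star,
    n_features = length(f_star),
    n_clusters = nrow(survivors),
    metrics = metrics
  )
}

#' Engine configuration
#'
#' Collects every tunable of the engine with the defaults of the reference
#' protocol: 90/10 outer split, top-1000 t-test screen, t = 10 inner 70/30
#' subsamples per cluster score, 10% intra-cluster pruning of clusters
#' larger than 5 features, random-forest learner with 100 trees, class
#' balancing by undersampling on.
#'
#' @param schedule Strictly decreasing integer vector of cluster counts;
#'   `NULL` uses `c(100, 90, 70, 50, 30, 20, 10, 5, 2)` (head capped at the
#'   filtered feature count at run time).
#' @param train_fraction Outer training fraction (default 0.9).
#' @param n_top Features kept by the t-test screen (default 1000).
#' @param ttest_variant `"welch"` (default) or `"pooled"`.
#' @param balance Undersample the majority class first (default `TRUE`).
#' @param t Inner subsamples per cluster score (default 10).
#' @param inner_train_fraction Inner training fraction (default 0.7).
#' @param f Intra-cluster removal percentage (default 10; 0 disables).
#' @param min_cluster_size_for_ife Clusters at most this size are never
#'   pruned (default 5).
#' @param learner `"random_forest"` (default) or `"svm"`.
#' @param ntree Trees per forest (default 100).
#' @param standardize Z-score features before k-means (default `TRUE`).
#' @param kmeans_restarts,kmeans_max_iter k-means settings (10, 300).
#' @return A named list of class `rceife_config`.
#' @export
rce_ife_config <- function(schedule = NULL, train_fraction = 0.9, n_top = 1000L,
                           ttest_variant = "welch", balance = TRUE,
                           t = 10L, inner_train_fraction = 0.7,
                           f = 10, min_cluster_size_for_ife = 5L,
                           learner = "random_forest", ntree = 100L,
                           standardize = TRUE,
                           kmeans_restarts = 10L, kmeans_max_iter = 300L) {
  if (!is.null(schedule)) check_schedule(schedule)
  structure(
    list(schedule = schedule, train_fraction = train_fraction, n_top = n_top,
         ttest_variant = ttest_variant, balance = balance, t = t,
         inner_train_fraction = inner_train_fraction, f = f,
         min_cluster_size_for_ife = min_cluster_size_for_ife,
         learner = match.arg(learner, learner_choices), ntree = ntree,
         standardize = standardize, kmeans_restarts = kmeans_restarts,
         kmeans_max_iter = kmeans_max_iter),
    class = "rceife_config"
  )
}

check_schedule <- function(schedule) {
  if (length(schedule) < 2L || any(diff(schedule) >= 0) || schedule[length(schedule)] < 1L) {
    abort("schedule must be >= 2 strictly decreasing positive integers.",
          class = "rceife_parameter_error")
  }
  invisible(schedule)
}

default_schedule <- c(100L, 90L, 70L, 50L, 30L, 20L, 10L, 5L, 2L)

# cap the schedule head at the filtered feature count, keeping it decreasing
cap_schedule <- function(schedule, n_features) {
  if (schedule[1L] > n_features) {
    warn(paste0("schedule head ", schedule[1L], " exceeds the ", n_features,
                " filtered features; capping."))
    schedule <- c(n_features, schedule[schedule < n_features])
  }
  check_schedule(schedule)
}

#' Run the full recursive cluster elimination with intra-cluster pruning
#'
#' One complete single-repetition run: optional undersampling, stratified
#' 90/10 outer split, two-sided t-test screen to the top `n_top` features,
#' then one [run_iteration()] per consecutive schedule pair. Feature sets
#' across levels are nested and non-increasing — an eliminated feature never
#' returns. The run records, per level, the surviving features and the full
#' metric set on the untouched outer test samples, plus each feature's
#' survival count (levels survived; features cut at the screen count 0).
#'
#' @param data A labeled tibble (see [as_labeled_data()]).
#' @param config An [rce_ife_config()]; individual `...` overrides are
#'   applied on top.
#' @param seed Master seed for the repetition.
#' @param ... Convenience overrides forwarded to [rce_ife_config()] when
#'   `config` is not given.
#' @return An object of class `rceife_run`: a list with `per_level` (tibble:
#'   `level`, `n_clusters`, `n_features`, the seven metrics),
#'   `surviving_features` (list of character vectors per level),
#'   `survival_count` (tibble: `feature_id`, `n_levels`), `schedule`,
#'   `config`, `seed`, and `seeds` (derived-seed manifest).
#' @export
#' @examples
#' sim <- simulate_blocks(20, 20, 60,
#'                        blocks = data.frame(size = 5, effect = 2, rho = 0.7),
#'                        seed = 4)
#' run <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 3, seed = 1)
#' tidy(run)
rce_ife <- function(data, config = NULL, seed = 1L, ...) {
  if (is.null(config)) config <- rce_ife_config(...)
  stopifnot(inherits(config, "rceife_config"))
  data <- as_labeled_data(data)
  check_two_class(data, "rce_ife")

  seeds <- list(undersample = derive_seed(seed, 101L),
                split = derive_seed(seed, 102L))
  if (config$balance) data <- undersample(data, seed = seeds$undersample)
  split <- stratified_split(data, config$train_fraction, seed = seeds$split)
  f0 <- ttest_filter(split$train, n_top = config$n_top, variant = config$ttest_variant)

  schedule <- if (is.null(config$schedule)) default_schedule else config$schedule
  schedule <- cap_schedule(schedule, length(f0))

  active <- f0
  levels_out <- vector("list", length(schedule) - 1L)
  for (i in seq_len(length(schedule) - 1L)) {
    it_seed <- derive_seed(seed, 200L, i)
    seeds[[paste0("iteration_", i)]] <- it_seed
    levels_out[[i]] <- run_iteration(
      split$train, split$test, active,
      m_i = schedule[i], m_next = schedule[i + 1L], config = config, seed = it_seed
    )
    active <- levels_out[[i]]$surviving_features
  }

  per_level <- purrr::map_dfr(levels_out, function(x) {
    dplyr::bind_cols(
      tibble::tibble(level = x$level, n_clusters = x$n_clusters,
                     n_features = x$n_features),
      x$metrics
    )
  })
  surv_tab <- table(unlist(purrr::map(levels_out, "surviving_features")))
  survival_count <- tibble::tibble(
    feature_id = feature_ids(data),
    n_levels = as.integer(surv_tab[feature_ids(data)])
  )
  survival_count$n_levels[is.na(survival_count$n_levels)] <- 0L

  structure(
    list(per_level = per_level,
         surviving_features = purrr::map(levels_out, "surviving_features"),
         survival_count = survival_count,
         schedule = schedule, config = config, seed = seed, seeds = seeds),
    class = "rceife_run"
  )
}

#' @export
print.rceife_run <- function(x, ...) {
  cat("RCE-IFE run (seed ", x$seed, ")\n", sep = "")
  cat("schedule:", paste(x$schedule, collapse = " > "), "\n")
  print(x$per_level)
  invisible(x)
}
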