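small_sim <- function(seed = 4) {
  simulate_blocks(20, 20, 120,
                  blocks = data.frame(size = c(6, 6), effect = 1.5, rho = 0.5),
                  seed = seed)
}

test_that("one iteration eliminates down to the schedule level before pruning", {
  sim <- small_sim()
  sp <- stratified_split(sim$data, 0.9, seed = 1)
  cfg <- rce_ife_config(t = 3)
  active <- ttest_filter(sp$train, n_top = 60)
  res <- run_iteration(sp$train, sp$test, active, m_i = 10, m_next = 6,
                       config = cfg, seed = 2)
  expect_equal(res$level, 6)
  expect_equal(res$n_clusters, 6L)
  expect_true(all(res$surviving_features %in% active))
  expect_lt(res$n_features, length(active))
  expect_gte(res$n_features, res$n_clusters) # every surviving cluster non-empty
  expect_s3_class(res$metrics, "tbl_df")
  expect_error(run_iteration(sp$train, sp$test, active, m_i = 5, m_next = 5,
                             config = cfg, seed = 2),
               class = "rceife_parameter_error")
})

test_that("pruning strictly shrinks the pool when all clusters are large", {
  sim <- small_sim(9)
  sp <- stratified_split(sim$data, 0.9, seed = 3)
  cfg <- rce_ife_config(t = 2)
  active <- ttest_filter(sp$train, n_top = 120)
  res <- run_iteration(sp$train, sp$test, active, m_i = 4, m_next = 3,
                       config = cfg, seed = 5)
  # 120 features in <= 4 clusters: survivors average 30 features, all > 5
  expect_lt(res$n_features, length(active))
})

test_that("full runs keep nested, non-increasing feature sets", {
  sim <- small_sim(12)
  run <- rce_ife(sim$data, schedule = c(15, 8, 4, 2), t = 3, n_top = 80, seed = 6)
  expect_equal(run$per_level$level, c(8, 4, 2))
  counts <- run$per_level$n_features
  expect_true(all(diff(counts) <= 0))
  sets <- run$surviving_features
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]])) # no resurrection
  }
  expect_true(all(run$per_level$n_features >= run$per_level$level))
  # survival counts agree with level membership
  expected <- table(unlist(sets))
  observed <- run$survival_count$n_levels[match(names(expected),
                                                run$survival_count$feature_id)]
  expect_equal(observed, as.integer(expected), ignore_attr = TRUE)
  expect_true(all(run$survival_count$n_levels[
    !run$survival_count$feature_id %in% names(expected)] == 0L))
})

test_that("runs are bit-identical under the same seed and differ across seeds", {
  sim <- small_sim(15)
  r1 <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 2, n_top = 50, seed = 8)
  r2 <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 2, n_top = 50, seed = 8)
  expect_identical(r1$per_level, r2$per_level)
  expect_identical(r1$surviving_features, r2$surviving_features)
  expect_identical(r1$survival_count, r2$survival_count)
  r3 <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 2, n_top = 50, seed = 9)
  expect_false(identical(r1$per_level, r3$per_level))
})

test_that("a schedule head above the filtered count is capped with a warning", {
  sim <- small_sim(18)
  expect_warning(
    run <- rce_ife(sim$data, schedule = c(100, 10, 2), t = 2, n_top = 40, seed = 1),
    regexp = "capping"
  )
  expect_equal(run$schedule[1], 40L)
  expect_equal(run$per_level$level, c(10, 2))
})

test_that("invalid schedules and labels are rejected", {
  sim <- small_sim(21)
  expect_error(rce_ife_config(schedule = c(5, 5, 2)), class = "rceife_parameter_error")
  expect_error(rce_ife_config(schedule = 7), class = "rceife_parameter_error")
  expect_error(rce_ife_config(schedule = c(5, 2, 3)), class = "rceife_parameter_error")
  one_class <- dplyr::filter(sim$data, label == "pos")
  expect_error(rce_ife(one_class, schedule = c(5, 2)), class = "rceife_label_error")
})

test_that("undersampling inside the run balances what the learner sees", {
  sim <- simulate_blocks(30, 12, 60,
                         blocks = data.frame(size = 4, effect = 1.5, rho = 0.4),
                         seed = 30)
  run <- rce_ife(sim$data, schedule = c(8, 4, 2), t = 2, n_top = 40,
                 balance = TRUE, seed = 2)
  expect_equal(run$per_level$level, c(4, 2))
  # balanced 12/12 then split 0.9: train 10/10, test 2/2
  expect_s3_class(run$per_level, "tbl_df")
  expect_true(all(!is.na(run$per_level$auc)))
})

test_that("the linear-SVM learner variant runs the full loop deterministically", {
  sim <- small_sim(25)
  r1 <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 2, n_top = 60,
                learner = "svm", seed = 4)
  r2 <- rce_ife(sim$data, schedule = c(10, 5, 2), t = 2, n_top = 60,
                learner = "svm", seed = 4)
  expect_identical(r1$per_level, r2$per_level)
  expect_equal(r1$per_level$level, c(5, 2))
  expect_true(all(r1$per_level$auc >= 0 & r1$per_level$auc <= 1))
  # |w| importance covers the cluster and is non-negative
  imp <- feature_importances(sim$informative, sim$data, learner = "svm", seed = 1)
  expect_setequal(imp$feature_id, sim$informative)
  expect_true(all(imp$importance >= 0))
})
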