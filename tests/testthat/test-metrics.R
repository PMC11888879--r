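test_that("confusion metrics match their printed formulas on worked examples", {
  perfect <- confusion_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_true(all(perfect == 1))
  wrong <- confusion_metrics(tp = 0, tn = 0, fp = 5, fn = 5)
  expect_equal(wrong$accuracy, 0)
  expect_equal(wrong$sensitivity, 0)
  expect_equal(wrong$specificity, 0)

  m <- confusion_metrics(tp = 40, fp = 10, tn = 45, fn = 5)
  expect_equal(m$accuracy, 0.85)
  expect_equal(round(m$sensitivity, 4), 0.8889)
  expect_equal(round(m$specificity, 4), 0.8182)
  expect_equal(m$precision, 0.80)
  expect_equal(round(m$f_measure, 4), 0.8421)
})

test_that("zero denominators are undefined, never zero", {
  m <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(m$sensitivity)) # no positives in truth
  expect_true(is.na(m$precision))   # no positive predictions
  expect_true(is.na(m$f_measure))
  expect_equal(m$accuracy, 1)
  expect_error(confusion_metrics(0, 0, 0, 0), class = "rceife_parameter_error")
  expect_error(confusion_metrics(-1, 1, 1, 1), class = "rceife_parameter_error")
})

test_that("cohen's kappa matches the margin formula and worked example", {
  expect_equal(cohen_kappa(tp = 10, fp = 0, tn = 7, fn = 0), 1)
  expect_equal(cohen_kappa(tp = 40, fp = 10, tn = 45, fn = 5), 0.70)
  # degenerate margins: everything one class, predicted as such
  expect_true(is.na(cohen_kappa(tp = 10, fp = 0, tn = 0, fn = 0)))
})

test_that("kappa is near zero for margin-matched independent predictions", {
  set.seed(5)
  kappas <- replicate(100, {
    truth <- sample(c("pos", "neg"), 1000, replace = TRUE, prob = c(0.6, 0.4))
    pred <- sample(c("pos", "neg"), 1000, replace = TRUE, prob = c(0.6, 0.4))
    tab <- table(factor(truth, c("pos", "neg")), factor(pred, c("pos", "neg")))
    cohen_kappa(tab["pos", "pos"], tab["neg", "pos"], tab["neg", "neg"], tab["pos", "neg"])
  })
  expect_lt(abs(mean(kappas)), 0.1)
  expect_gt(mean(abs(kappas) < 0.1), 0.95)
})

test_that("auc equals the pairwise concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c("pos", "pos", "neg", "neg")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("pos", "neg"), 3)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c("pos", "pos", "neg", "neg")), 0.75)
  expect_error(roc_auc(1:3, c("pos", "pos", "pos")), class = "rceife_metric_error")
  expect_error(roc_auc(1:3, c("pos", "neg")), class = "rceife_parameter_error")
})

test_that("auc agrees with brute force and pROC on random score vectors", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- rep("neg", n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- "pos"
    scores <- round(stats::rnorm(n), 1) # coarse grid to exercise ties
    a <- roc_auc(scores, labels)
    expect_equal(a, oracle_auc(scores, labels))
    p <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c("neg", "pos"), direction = "<", quiet = TRUE
    )))
    expect_equal(a, p)
  }
})

test_that("all metrics agree with the brute-force oracle on random tables", {
  set.seed(7)
  for (i in 1:1000) {
    counts <- as.integer(stats::rmultinom(1, sample(1:60, 1), rep(0.25, 4)))
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    m <- confusion_metrics(tp, fp, tn, fn)
    o <- oracle_confusion(tp, fp, tn, fn)
    for (name in c("accuracy", "sensitivity", "specificity", "precision", "f_measure")) {
      expect_equal(m[[name]], o[[name]], info = name)
    }
    k <- cohen_kappa(tp, fp, tn, fn)
    if (!is.na(k) && !is.na(o$kappa)) expect_equal(k, o$kappa)
    # harmonic-mean identity
    if (!anyNA(c(m$precision, m$sensitivity)) && m$precision + m$sensitivity > 0) {
      expect_equal(m$f_measure,
                   2 * m$precision * m$sensitivity / (m$precision + m$sensitivity))
    }
  }
})

test_that("swapping class roles swaps sensitivity/specificity and flips auc", {
  set.seed(13)
  for (i in 1:20) {
    counts <- as.integer(stats::rmultinom(1, 40, rep(0.25, 4))) + 1L
    m <- confusion_metrics(counts[1], counts[2], counts[3], counts[4])
    swapped <- confusion_metrics(counts[3], counts[4], counts[1], counts[2])
    expect_equal(m$sensitivity, swapped$specificity)
    expect_equal(m$specificity, swapped$sensitivity)

    n <- 20
    labels <- rep(c("pos", "neg"), 10)
    scores <- stats::rnorm(n)
    flipped <- ifelse(labels == "pos", "neg", "pos")
    expect_equal(roc_auc(scores, labels), 1 - roc_auc(scores, flipped))
  }
})

test_that("classification_metrics assembles the full per-level set", {
  truth <- c("pos", "pos", "pos", "neg", "neg", "neg")
  est <- c("pos", "pos", "neg", "neg", "neg", "pos")
  scores <- c(0.9, 0.8, 0.4, 0.2, 0.1, 0.6)
  m <- classification_metrics(truth, est, scores)
  expect_named(m, c("accuracy", "sensitivity", "specificity", "precision",
                    "f_measure", "auc", "kappa"))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$auc, oracle_auc(scores, truth))
  expect_equal(m$kappa, cohen_kappa(2, 1, 2, 1))
})
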