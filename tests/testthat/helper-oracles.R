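# Independent oracles used by both the unit and acceptance suites. Each
# recomputes a quantity by brute force or by a different library, never by
# calling the code path it checks.

# rebuild label/prediction vectors from the counts and recompute every
# confusion metric by direct counting; kappa via e1071's independent
# implementation
oracle_confusion <- function(tp, fp, tn, fn) {
  truth <- rep(c("pos", "pos", "neg", "neg"), c(tp, fn, tn, fp))
  pred <- rep(c("pos", "neg", "neg", "pos"), c(tp, fn, tn, fp))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    accuracy = mean(truth == pred),
    sensitivity = safe(sum(truth == "pos" & pred == "pos"), sum(truth == "pos")),
    specificity = safe(sum(truth == "neg" & pred == "neg"), sum(truth == "neg")),
    precision = safe(sum(truth == "pos" & pred == "pos"), sum(pred == "pos")),
    f_measure = safe(2 * sum(truth == "pos" & pred == "pos"),
                     2 * sum(truth == "pos" & pred == "pos") +
                       sum(pred == "pos" & truth == "neg") +
                       sum(pred == "neg" & truth == "pos")),
    kappa = e1071::classAgreement(table(factor(truth, c("pos", "neg")),
                                        factor(pred, c("pos", "neg"))))$kappa
  )
}

# brute-force AUC: count concordant positive-negative pairs, ties as 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "pos"]
  neg <- scores[labels == "neg"]
  total <- 0
  for (p in pos) for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# independent re-computation of a cluster score: materialize the t split
# index sets with the exported split rule and the same derived seeds, fit the
# forest directly, and average accuracies by hand
score_cluster_oracle <- function(feats, train, t, seed, ntree = 100) {
  sub <- build_subdataset(train, feats)
  accs <- numeric(t)
  for (i in seq_len(t)) {
    sp <- stratified_split(sub, 0.7, seed = derive_seed(seed, i, 1L))
    x_tr <- as.matrix(sp$train[feats])
    x_te <- as.matrix(sp$test[feats])
    set.seed(derive_seed(seed, i, 2L))
    fit <- randomForest::randomForest(x = x_tr, y = sp$train$label, ntree = ntree)
    accs[i] <- mean(as.character(predict(fit, x_te)) == as.character(sp$test$label))
  }
  mean(accs)
}
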