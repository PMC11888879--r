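# Thin wrappers around the two supported learner families. Everything the
# engine needs from a classifier is: fit, predicted class, a positive-class
# score for AUC, and per-feature importance weights.

learner_choices <- c("random_forest", "svm")

fit_learner <- function(train, learner = "random_forest", seed = 1L,
                        ntree = 100L, cost = 1) {
  learner <- match.arg(learner, learner_choices)
  x <- feature_matrix(train)
  y <- train$label
  model <- with_seed(seed, {
    if (learner == "random_forest") {
      randomForest::randomForest(x = x, y = y, ntree = ntree, importance = FALSE)
    } else {
      # scale = FALSE tolerates constant columns after restriction
      e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
    }
  })
  structure(list(model = model, learner = learner, features = feature_ids(train)),
            class = "rceife_fit")
}

predict_class <- function(fit, data) {
  x <- feature_matrix(restrict_features(data, fit$features))
  factor(as.character(predict(fit$model, x)), levels = label_levels)
}

# positive-class score: class probability for RF, decision value for SVM
predict_score <- function(fit, data) {
  x <- feature_matrix(restrict_features(data, fit$features))
  if (fit$learner == "random_forest") {
    unname(predict(fit$model, x, type = "prob")[, "pos"])
  } else {
    dv <- attr(predict(fit$model, x, decision.values = TRUE), "decision.values")
    v <- dv[, 1L]
    # orient so larger means more 'pos', whatever the internal level order
    if (!grepl("^pos", colnames(dv)[1L])) v <- -v
    unname(v)
  }
}

# per-feature importance: mean impurity decrease for RF, |w| for linear SVM
learner_importance <- function(fit) {
  if (fit$learner == "random_forest") {
    imp <- randomForest::importance(fit$model, type = 2L)[, 1L]
  } else {
    m <- fit$model
    w <- crossprod(m$coefs, m$SV)[1L, ]
    imp <- abs(w)
  }
  out <- rep(0, length(fit$features))
  names(out) <- fit$features
  out[names(imp)] <- unname(imp)
  out
}
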