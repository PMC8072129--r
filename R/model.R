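# Gradient-boosted screening classifier and its evaluation artifacts.
# The boosted-tree learner itself is delegated to xgboost — it is the one
# off-the-shelf stage of the pipeline; everything the evaluation depends on
# (rank AUC, split-count importances, learning and incremental-feature
# curves, false-negative profiling) is implemented here.

#' Gradient-boosting configuration
#'
#' Defaults are the screening model's tuned operating point: shallow trees
#' (`max_depth` 3), slow learning rate 0.07 over 150 rounds, positive class
#' upweighted 2x to counter the ~23% prevalence, and mild regularization
#' (`min_child_weight` 6, `gamma` 0.2, `reg_alpha` 0.1).
#'
#' @param max_depth Tree depth.
#' @param learning_rate Shrinkage per boosting round.
#' @param n_estimators Number of boosting rounds.
#' @param scale_pos_weight Weight multiplier of the positive class.
#' @param min_child_weight Minimum hessian sum per leaf.
#' @param gamma Minimum loss reduction to split.
#' @param reg_alpha L1 penalty on leaf weights.
#' @param seed Integer seed (single-threaded training is deterministic).
#' @param nthread Training threads (default 1 for reproducibility).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(max_depth = 3L,
                              learning_rate = 0.07,
                              n_estimators = 150L,
                              scale_pos_weight = 2,
                              min_child_weight = 6,
                              gamma = 0.2,
                              reg_alpha = 0.1,
                              seed = 1L,
                              nthread = 1L) {
  if (n_estimators < 0) stop("n_estimators must be >= 0")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(max_depth = as.integer(max_depth),
                 learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 scale_pos_weight = scale_pos_weight,
                 min_child_weight = min_child_weight,
                 gamma = gamma,
                 reg_alpha = reg_alpha,
                 seed = as.integer(seed),
                 nthread = as.integer(nthread)),
            class = "classifier_config")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) estimator with ties counted one half: the
#' probability that a uniformly chosen positive is scored above a uniformly
#' chosen negative.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class is absent")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the boosted screening classifier
#'
#' Fits an xgboost binary:logistic model on the feature matrix with the
#' configured hyperparameters. Same data, configuration and seed reproduce
#' identical scores.
#'
#' @param train Complete (imputed) labeled training table.
#' @param config A [classifier_config()].
#' @param features Predictor columns (default: everything except `fld`).
#' @return An object of class `fld_model` exposing per-row scores via
#'   [predict()] and per-feature split counts via [feature_importance()].
#' @export
train_classifier <- function(train, config = classifier_config(),
                             features = setdiff(names(train), "fld")) {
  y <- train$fld
  if (length(unique(y)) < 2) stop("training data contains a single class")
  x <- as.matrix(train[features])
  booster <- NULL
  if (config$n_estimators > 0) {
    params <- xgboost::xgb.params(
      objective = "binary:logistic",
      max_depth = config$max_depth,
      learning_rate = config$learning_rate,
      scale_pos_weight = config$scale_pos_weight,
      min_child_weight = config$min_child_weight,
      gamma = config$gamma,
      reg_alpha = config$reg_alpha,
      nthread = config$nthread,
      seed = config$seed
    )
    booster <- xgboost::xgb.train(params = params,
                                  data = xgboost::xgb.DMatrix(x, label = y, nthread = config$nthread),
                                  nrounds = config$n_estimators, verbose = 0)
  }
  structure(list(booster = booster, features = features, config = config),
            class = "fld_model")
}

#' @param object,newdata,... An `fld_model`, a table with its feature
#'   columns, and ignored extras.
#' @rdname train_classifier
#' @export
predict.fld_model <- function(object, newdata, ...) {
  if (is.null(object$booster)) return(rep(0.5, nrow(newdata)))
  stats::predict(object$booster, as.matrix(newdata[object$features]))
}

#' Split-count feature importance
#'
#' The importance of a feature is the number of times it is chosen as a split
#' variable across the whole ensemble; features never used count 0. The list
#' is sorted by descending count, ties broken alphabetically, and the counts
#' sum to the total number of splits.
#'
#' @param model An `fld_model`.
#' @return Data frame with columns `feature` and `count`.
#' @export
feature_importance <- function(model) {
  counts <- stats::setNames(rep(0L, length(model$features)), model$features)
  if (!is.null(model$booster)) {
    trees <- xgboost::xgb.model.dt.tree(model$booster)
    used <- table(trees$Feature[trees$Feature != "Leaf"])
    counts[names(used)] <- as.integer(used)
  }
  out <- data.frame(feature = names(counts), count = unname(counts))
  out <- out[order(-out$count, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Train/test AUC as a function of boosting rounds
#'
#' Refits the model at each grid value of `n_estimators` and records train
#' and test AUC — the bias–variance diagnostic: train AUC rises with
#' capacity while test AUC flattens or drops when overfitting sets in.
#'
#' @param train,test Complete labeled tables.
#' @param config A [classifier_config()].
#' @param grid Ascending positive integers (rounds).
#' @param features Predictor columns.
#' @return Data frame with columns `n_estimators`, `train_auc`, `test_auc`.
#' @export
learning_curve <- function(train, test, config = classifier_config(),
                           grid = c(10, 25, 50, 100, 150, 250),
                           features = setdiff(names(train), "fld")) {
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and strictly ascending")
  rows <- lapply(grid, function(g) {
    cfg <- config
    cfg$n_estimators <- as.integer(g)
    m <- train_classifier(train, cfg, features)
    data.frame(n_estimators = g,
               train_auc = auc(predict(m, train), train$fld),
               test_auc = auc(predict(m, test), test$fld))
  })
  do.call(rbind, rows)
}

#' Test AUC as top-ranked features are added one at a time
#'
#' For `m = 1..max_m` the model is retrained on the `m` most important
#' features only and its held-out AUC recorded — showing how few exam items
#' suffice for screening-grade discrimination.
#'
#' @param train,test Complete labeled tables.
#' @param config A [classifier_config()].
#' @param ranked_features Feature names in importance order (e.g. from
#'   [feature_importance()]).
#' @param max_m How far down the ranking to go (default: all).
#' @return Data frame with columns `m`, `feature_added`, `test_auc`.
#' @export
incremental_feature_curve <- function(train, test, config = classifier_config(),
                                      ranked_features,
                                      max_m = length(ranked_features)) {
  if (max_m > length(ranked_features)) stop("max_m exceeds the ranking length")
  rows <- lapply(seq_len(max_m), function(m) {
    mdl <- train_classifier(train, config, features = ranked_features[seq_len(m)])
    data.frame(m = m, feature_added = ranked_features[m],
               test_auc = auc(predict(mdl, test), test$fld))
  })
  do.call(rbind, rows)
}

#' Profile the missed FLD patients
#'
#' Compares per-feature means and standard deviations of false-negative
#' positives (label 1 scored below `threshold`) with all positives — the
#' patients a screening model misses tend to be those whose exam indicators
#' look normal.
#'
#' @param test Labeled test table.
#' @param scores Model scores for `test` rows.
#' @param threshold Classification threshold in (0,1), default 0.5.
#' @return A list with `n_positives`, `n_false_negatives`, `threshold`, and
#'   `table` (per-feature means/SDs in the two groups).
#' @export
false_negative_summary <- function(test, scores, threshold = 0.5) {
  pos <- which(test$fld == 1)
  if (length(pos) == 0)
    return(list(n_positives = 0L, n_false_negatives = 0L,
                threshold = threshold, table = NULL))
  fn <- pos[scores[pos] < threshold]
  feats <- c("age", feature_columns(test))
  tab <- do.call(rbind, lapply(feats, function(f) data.frame(
    feature = f,
    mean_false_negative = if (length(fn)) mean(test[[f]][fn], na.rm = TRUE) else NA_real_,
    sd_false_negative = if (length(fn) > 1) stats::sd(test[[f]][fn], na.rm = TRUE) else NA_real_,
    mean_positive = mean(test[[f]][pos], na.rm = TRUE),
    sd_positive = stats::sd(test[[f]][pos], na.rm = TRUE)
  )))
  rownames(tab) <- NULL
  list(n_positives = length(pos), n_false_negatives = length(fn),
       threshold = threshold, table = tab)
}

#' Stratified k-fold cross-validated AUC
#'
#' A plain harness for manual hyperparameter exploration: stratified folds,
#' one AUC per held-out fold.
#'
#' @param table Complete labeled table.
#' @param config A [classifier_config()].
#' @param k Number of folds (default 3).
#' @param seed Fold-assignment seed.
#' @param features Predictor columns.
#' @return A list with `fold_auc` (length `k`) and `mean_auc`.
#' @export
cv_auc <- function(table, config = classifier_config(), k = 3L, seed = 1L,
                   features = setdiff(names(table), "fld")) {
  folds <- withr::with_seed(seed, {
    f <- integer(nrow(table))
    for (cls in unique(table$fld)) {
      ix <- which(table$fld == cls)
      f[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    f
  })
  fold_auc <- vapply(seq_len(k), function(i) {
    m <- train_classifier(table[folds != i, , drop = FALSE], config, features)
    held <- table[folds == i, , drop = FALSE]
    auc(predict(m, held), held$fld)
  }, 0)
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc))
}
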