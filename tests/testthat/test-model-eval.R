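test_that("rank AUC matches the exhaustive pair-enumeration oracle", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               tolerance = 1e-12)
  withr::with_seed(81, {
    for (i in 1:100) {
      n <- sample(6:30, 1)
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # many ties
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC has the contracted boundary and invariance behavior", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(auc(c(1, 2, 3, 4, 5), y), 1)            # perfect separation
  expect_equal(auc(rep(0.3, 5), y), 0.5)               # all tied
  s <- c(0.2, 0.9, 0.1, 0.6, 0.8)
  expect_equal(auc(plogis(5 * s - 2), y), auc(s, y))   # monotone transform
  expect_equal(auc(-s, y), 1 - auc(s, y))              # score negation
  expect_error(auc(s, rep(1, 5)), "one class")
})

test_that("classifier training is deterministic and fits separable data", {
  withr::with_seed(91, {
    x <- c(rnorm(100, 0), rnorm(100, 8))               # far-separated classes
    tab <- data.frame(sex = rbinom(200, 1, 0.5), age = sample(20:80, 200, TRUE),
                      fld = rep(0:1, each = 100), marker = x)
  })
  m <- train_classifier(tab, classifier_config(seed = 4))
  expect_equal(auc(predict(m, tab), tab$fld), 1)       # separable: train AUC 1

  m2 <- train_classifier(tab, classifier_config(seed = 4))
  expect_identical(predict(m2, tab), predict(m, tab))

  expect_error(train_classifier(within(tab, fld <- 0), classifier_config()),
               "single class")
})

test_that("permuted labels give chance-level held-out AUC", {
  aucs <- vapply(1:10, function(s) {
    withr::with_seed(900 + s, {
      tab <- data.frame(sex = rbinom(2000, 1, 0.5),
                        age = sample(20:80, 2000, TRUE),
                        fld = sample(rep(0:1, 1000)),   # label independent
                        a = rnorm(2000), b = rnorm(2000), c = rnorm(2000))
    })
    sp <- split_train_test(tab, prep_config(split_seed = s))
    m <- train_classifier(sp$train, classifier_config(seed = s))
    auc(predict(m, sp$test), sp$test$fld)
  }, 0)
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("learning curve train AUC rises with boosting rounds", {
  withr::with_seed(92, {
    tab <- data.frame(sex = rbinom(300, 1, 0.5), age = sample(20:80, 300, TRUE),
                      fld = rbinom(300, 1, 0.4), x = rnorm(300))
    tab$fld <- as.integer(tab$x + rnorm(300, 0, 2) > 0)
  })
  sp <- split_train_test(tab, prep_config(split_seed = 1))
  lc <- learning_curve(sp$train, sp$test, classifier_config(seed = 1),
                       grid = c(1, 10, 100))
  expect_equal(nrow(lc), 3)
  expect_true(all(diff(lc$train_auc) >= 0))            # monotone in capacity

  one <- learning_curve(sp$train, sp$test, classifier_config(seed = 1), grid = 1)
  cfg1 <- classifier_config(seed = 1); cfg1$n_estimators <- 1L
  direct <- train_classifier(sp$train, cfg1)
  expect_equal(one$test_auc, auc(predict(direct, sp$test), sp$test$fld))

  expect_error(learning_curve(sp$train, sp$test, grid = c(10, 5)), "ascending")
})

test_that("split-count importance ranks the planted feature first", {
  first <- vapply(1:10, function(s) {
    withr::with_seed(700 + s, {
      tab <- data.frame(sex = rbinom(600, 1, 0.5), age = sample(20:80, 600, TRUE),
                        signal = rnorm(600))
      tab <- cbind(tab, as.data.frame(matrix(rnorm(600 * 9), 600,
                                             dimnames = list(NULL, paste0("n", 1:9)))))
      tab$fld <- as.integer(tab$signal + rnorm(600, 0, 0.8) > 0)
    })
    m <- train_classifier(tab, classifier_config(seed = s))
    feature_importance(m)$feature[1]
  }, "")
  expect_gte(sum(first == "signal"), 9)
})

test_that("importance counts are consistent, ordered and sum to total splits", {
  tab <- make_fixture_cohort(300, seed = 93)
  m <- train_classifier(tab, classifier_config(seed = 2))
  imp <- feature_importance(m)
  expect_setequal(imp$feature, m$features)
  expect_true(all(imp$count >= 0))
  expect_true(all(imp$count == as.integer(imp$count)))
  trees <- xgboost::xgb.model.dt.tree(m$booster)
  expect_equal(sum(imp$count), sum(trees$Feature != "Leaf"))
  resorted <- imp[order(-imp$count, imp$feature), ]
  rownames(resorted) <- NULL
  expect_identical(resorted, imp)                      # idempotent ordering

  empty_cfg <- classifier_config(); empty_cfg$n_estimators <- 0L
  m0 <- train_classifier(tab, empty_cfg)
  imp0 <- feature_importance(m0)
  expect_true(all(imp0$count == 0))
  expect_equal(predict(m0, tab), rep(0.5, nrow(tab)))
})

test_that("incremental curve at full feature count equals the full model", {
  tab <- make_fixture_cohort(400, seed = 94)
  sp <- split_train_test(tab, prep_config(split_seed = 4))
  cfg <- classifier_config(seed = 4)
  m <- train_classifier(sp$train, cfg)
  ranked <- feature_importance(m)$feature
  curve <- incremental_feature_curve(sp$train, sp$test, cfg, ranked)
  expect_equal(nrow(curve), length(ranked))
  full_auc <- auc(predict(train_classifier(sp$train, cfg, features = ranked),
                          sp$test), sp$test$fld)
  expect_equal(curve$test_auc[length(ranked)], full_auc)
  expect_gt(curve$test_auc[1], 0.5)                    # single planted marker
  expect_error(incremental_feature_curve(sp$train, sp$test, cfg, ranked,
                                         max_m = length(ranked) + 1), "max_m")
})

test_that("false-negative summary honors the threshold boundaries", {
  tab <- make_fixture_cohort(200, seed = 95)
  scores <- withr::with_seed(1, runif(200, 0.01, 0.99))
  none <- false_negative_summary(tab, scores, threshold = 0)
  expect_equal(none$n_false_negatives, 0)              # all predicted positive
  all_fn <- false_negative_summary(tab, scores, threshold = 1)
  expect_equal(all_fn$n_false_negatives, all_fn$n_positives)
  expect_equal(all_fn$table$mean_false_negative, all_fn$table$mean_positive)

  no_pos <- tab; no_pos$fld <- 0
  empty <- false_negative_summary(no_pos, scores)
  expect_equal(empty$n_positives, 0)
  expect_null(empty$table)
})

test_that("3-fold cross-validation returns one AUC per fold", {
  tab <- make_fixture_cohort(300, seed = 96)
  res <- cv_auc(tab, classifier_config(seed = 1), k = 3, seed = 5)
  expect_length(res$fold_auc, 3)
  expect_true(all(res$fold_auc > 0 & res$fold_auc < 1))
  expect_equal(res$mean_auc, mean(res$fold_auc))
  res2 <- cv_auc(tab, classifier_config(seed = 1), k = 3, seed = 5)
  expect_identical(res, res2)
})
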