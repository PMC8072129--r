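# End-to-end screening workflow: simulate (or load) -> filter unlabeled ->
# drop sparse items -> 70/30 split -> ChiMerge age bins on the training
# split -> group-median imputation -> min-max normalization -> GP feature
# synthesis -> boosted classifier -> evaluation report, with every fitted
# object written as a human-inspectable JSON/CSV artifact.

#' Assemble a full pipeline configuration
#'
#' One global seed deterministically derives the per-stage seeds, so each
#' stage is individually reproducible.
#'
#' @param seed Global seed.
#' @param n_samples Cohort size when simulating.
#' @param use_gp Run the genetic-programming feature stage (default `TRUE`).
#' @param target_bins Number of ChiMerge age bins (default 5).
#' @param cohort,prep,gp,classifier Stage configurations; defaults are
#'   derived from `seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_samples = 10000L,
                            use_gp = TRUE,
                            target_bins = 5L,
                            cohort = cohort_config(n_samples = n_samples,
                                                   seed = stage_seed(seed, 11)),
                            prep = prep_config(split_seed = stage_seed(seed, 12)),
                            gp = gp_config(seed = stage_seed(seed, 13)),
                            classifier = classifier_config(seed = stage_seed(seed, 14))) {
  structure(list(seed = as.integer(seed), use_gp = isTRUE(use_gp),
                 target_bins = as.integer(target_bins),
                 cohort = cohort, prep = prep, gp = gp, classifier = classifier),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds flat key-value sections (`cohort:`, `prep:`, `gp:`,
#' `classifier:`) plus top-level `seed`, `n_samples`, `use_gp`,
#' `target_bins`; every key is optional and overrides the derived default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  cfg <- pipeline_config(seed = seed,
                         n_samples = as.integer(y$n_samples %||% 10000L),
                         use_gp = y$use_gp %||% TRUE,
                         target_bins = as.integer(y$target_bins %||% 5L))
  for (sec in c("cohort", "prep", "gp", "classifier")) {
    if (!is.null(y[[sec]])) {
      cls <- class(cfg[[sec]])
      cfg[[sec]] <- structure(utils::modifyList(unclass(cfg[[sec]]), y[[sec]]),
                              class = cls)
    }
  }
  cfg
}

#' Run the whole screening pipeline
#'
#' Executes every stage in order and returns the evaluation report. When
#' `out_dir` is given, all fitted artifacts are written there:
#' `binning_scheme.json`, `imputation_plan.json`, `gp_features.json`,
#' `class_summary.csv`, `feature_importance.csv`,
#' `false_negative_summary.csv` and `report.json`. Re-running with the same
#' configuration reproduces the artifacts bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param input Optional cohort: a data frame or a CSV path (as written by
#'   [write_cohort_csv()]). `NULL` simulates a cohort from
#'   `config$cohort`.
#' @param out_dir Optional artifact directory (created if missing).
#' @param verbose Print stage progress.
#' @return A list of class `fld_report`: train/test AUC, the fitted binning
#'   scheme, GP features, ranked importances, false-negative summary,
#'   dropped columns and cohort bookkeeping.
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  tab <- if (is.null(input)) {
    say("simulating cohort: n = ", config$cohort$n_samples)
    inject_missingness(generate_cohort(config$cohort), config$cohort)
  } else if (is.character(input)) {
    read_cohort_csv(input)
  } else {
    input
  }

  tab <- filter_unlabeled(tab)
  say("labeled rows: ", nrow(tab), "; prevalence ",
      sprintf("%.3f", mean(tab$fld)))
  ds <- drop_sparse_features(tab, config$prep)
  tab <- ds$table
  say("dropped sparse columns: ",
      if (length(ds$dropped)) paste(ds$dropped, collapse = ", ") else "none")
  summary_tab <- class_summary(tab)

  sp <- split_train_test(tab, config$prep)
  scheme <- fit_chimerge(sp$train$age, sp$train$fld, config$target_bins)
  say("age bins: ", scheme$n_bins, " (cuts ",
      paste(scheme$cuts, collapse = ", "), "); merges: ", scheme$n_merges)

  plan <- fit_imputer(sp$train, scheme)
  train <- apply_imputer(plan, sp$train)
  test <- apply_imputer(plan, sp$test)

  norm_cols <- c(feature_columns(train), "age")
  train_n <- normalize_features(train, train, norm_cols)
  test_n <- normalize_features(train, test, norm_cols)

  gp <- NULL
  if (config$use_gp) {
    gp <- run_gp(train_n, train_n$fld, config$gp,
                 features = c(feature_columns(train_n), "age", "sex"))
    for (i in seq_along(gp$features))
      say(sprintf("GA_fea%d = %s  (fitness %.4f)", i,
                  gp$features[[i]]$expression, gp$features[[i]]$fitness))
    train_n <- append_gp_features(train_n, gp)
    test_n <- append_gp_features(test_n, gp)
  }

  model <- train_classifier(train_n, config$classifier)
  train_scores <- predict(model, train_n)
  test_scores <- predict(model, test_n)
  train_auc <- auc(train_scores, train_n$fld)
  test_auc <- auc(test_scores, test_n$fld)
  say(sprintf("train AUC %.4f | test AUC %.4f  (hyperparameters: depth %d, ",
              train_auc, test_auc, config$classifier$max_depth),
      sprintf("eta %.3f, %d rounds)", config$classifier$learning_rate,
              config$classifier$n_estimators))
  importance <- feature_importance(model)
  fn <- false_negative_summary(test_n, test_scores)

  report <- structure(list(
    train_auc = train_auc, test_auc = test_auc,
    scheme = scheme, gp = gp, importance = importance,
    false_negatives = fn, class_summary = summary_tab,
    dropped_columns = ds$dropped,
    n_labeled = nrow(tab), n_train = nrow(train), n_test = nrow(test),
    prevalence = mean(tab$fld), model = model, config = config
  ), class = "fld_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scheme_json(scheme, file.path(out_dir, "binning_scheme.json"))
    write_imputation_json(plan, file.path(out_dir, "imputation_plan.json"))
    if (!is.null(gp))
      write_gp_features_json(gp, file.path(out_dir, "gp_features.json"))
    utils::write.csv(summary_tab, file.path(out_dir, "class_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(importance, file.path(out_dir, "feature_importance.csv"),
                     row.names = FALSE)
    if (!is.null(fn$table))
      utils::write.csv(fn$table, file.path(out_dir, "false_negative_summary.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(
      train_auc = train_auc, test_auc = test_auc,
      prevalence = report$prevalence, n_labeled = report$n_labeled,
      n_train = report$n_train, n_test = report$n_test,
      dropped_columns = ds$dropped,
      age_cuts = scheme$cuts,
      gp_features = if (!is.null(gp)) lapply(gp$features, function(f)
        list(expression = f$expression, fitness = f$fitness)),
      n_false_negatives = fn$n_false_negatives
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.fld_report <- function(x, ...) {
  cat("FLD screening pipeline report\n")
  cat(sprintf("  labeled rows: %d (prevalence %.3f); train %d / test %d\n",
              x$n_labeled, x$prevalence, x$n_train, x$n_test))
  cat("  age bins:", paste(x$scheme$cuts, collapse = ", "),
      "(", x$scheme$n_bins, "bins )\n")
  if (!is.null(x$gp))
    for (i in seq_along(x$gp$features))
      cat(sprintf("  GA_fea%d = %s  (fitness %.4f)\n", i,
                  x$gp$features[[i]]$expression, x$gp$features[[i]]$fitness))
  cat(sprintf("  train AUC %.4f | test AUC %.4f\n", x$train_auc, x$test_auc))
  top <- utils::head(x$importance, 5)
  cat("  top features by split count:",
      paste(sprintf("%s(%d)", top$feature, top$count), collapse = ", "), "\n")
  invisible(x)
}
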