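# Cohort preprocessing: drop unlabeled patients, drop sparse exam items,
# stratified 70/30 split, and the per-class summary with chi-square
# significance flags.

#' Preprocessing configuration
#'
#' @param max_missing_fraction Drop a feature when its missing fraction
#'   exceeds this (default 2/3). Used when `mode = "fraction"`.
#' @param max_missing_count Drop a feature when its absolute missing count
#'   exceeds this. Used when `mode = "count"`.
#' @param mode `"fraction"` (default) or `"count"`.
#' @param train_fraction Fraction of rows assigned to the training split.
#' @param split_seed Seed of the random split.
#' @param stratify Stratify the split by label (default `TRUE`), keeping
#'   per-class proportions within one sample of the global split.
#' @return A list of class `prep_config`.
#' @export
prep_config <- function(max_missing_fraction = 2 / 3,
                        max_missing_count = NULL,
                        mode = c("fraction", "count"),
                        train_fraction = 0.7,
                        split_seed = 1L,
                        stratify = TRUE) {
  mode <- match.arg(mode)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly inside (0, 1)")
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]")
  if (mode == "count" && is.null(max_missing_count))
    stop("mode = 'count' requires max_missing_count")
  structure(list(max_missing_fraction = max_missing_fraction,
                 max_missing_count = max_missing_count,
                 mode = mode,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 stratify = isTRUE(stratify)),
            class = "prep_config")
}

#' Drop patients without an ultrasound record
#'
#' Rows whose label is absent carry no diagnostic information and are removed;
#' row order is preserved.
#'
#' @param table A cohort data frame with an `fld` column.
#' @return The labeled subset.
#' @export
filter_unlabeled <- function(table) {
  keep <- !is.na(table$fld)
  if (!any(keep)) stop("empty cohort: no labeled rows remain")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop exam items that most patients never had
#'
#' Features whose missingness exceeds the configured threshold are removed;
#' `sex`, `age` and the label are never dropped.
#'
#' @param table A cohort data frame.
#' @param config A [prep_config()].
#' @return A list with `table` (retained columns) and `dropped` (names).
#' @export
drop_sparse_features <- function(table, config = prep_config()) {
  feats <- feature_columns(table)
  n_miss <- vapply(table[feats], function(x) sum(is.na(x)), 0L)
  drop <- if (config$mode == "fraction") {
    n_miss / nrow(table) > config$max_missing_fraction
  } else {
    n_miss > config$max_missing_count
  }
  dropped <- feats[drop]
  list(table = table[, setdiff(names(table), dropped), drop = FALSE],
       dropped = dropped)
}

#' Split a labeled cohort into training and test sets
#'
#' The training set has `round(train_fraction * n)` rows. Under
#' stratification each class contributes within one sample of its
#' proportional share (largest-remainder allocation).
#'
#' @param table A labeled cohort data frame (no absent labels).
#' @param config A [prep_config()].
#' @return A list with data frames `train` and `test`.
#' @export
split_train_test <- function(table, config = prep_config()) {
  n <- nrow(table)
  if (any(is.na(table$fld))) stop("split requires a fully labeled table")
  target <- round(config$train_fraction * n)
  idx <- withr::with_seed(config$split_seed, {
    if (config$stratify) {
      by_class <- split(seq_len(n), table$fld)
      if (length(by_class) < 2 || any(lengths(by_class) < 2))
        stop("stratified split needs at least 2 rows in each class")
      quota <- config$train_fraction * lengths(by_class)
      take <- floor(quota)
      extra <- target - sum(take)
      if (extra > 0) {
        ord <- order(quota - take, decreasing = TRUE)
        take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
      }
      sort(unlist(mapply(function(ix, k) sample(ix, k),
                         by_class, take, SIMPLIFY = FALSE), use.names = FALSE))
    } else {
      sort(sample.int(n, target))
    }
  })
  train <- table[idx, , drop = FALSE]
  test <- table[-idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}

#' Per-class feature summary with chi-square significance flags
#'
#' For every feature (plus `age` and `sex`) the mean and standard deviation
#' within the FLD and non-FLD groups are computed on observed values, and
#' association with the label is tested by a chi-square independence test on
#' the quartile-binned feature (4 bins on pooled observed values; `sex` is
#' used with its two natural levels). Features with fewer than `min_obs`
#' observed values, or too few distinct values to bin, are reported untested.
#'
#' @param table A labeled cohort data frame with both classes present.
#' @param alpha Significance level for the flag (default 0.05).
#' @param min_obs Minimum observed values required to run the test.
#' @return A data frame with one row per feature: group means/SDs, test
#'   statistic, p-value, `significant` flag and `tested` indicator.
#' @export
class_summary <- function(table, alpha = 0.05, min_obs = 8L) {
  y <- table$fld
  if (length(unique(y[!is.na(y)])) < 2) stop("both classes must be present")
  feats <- c("sex", "age", feature_columns(table))
  rows <- lapply(feats, function(nm) {
    x <- table[[nm]]
    obs <- !is.na(x) & !is.na(y)
    xv <- x[obs]; yv <- y[obs]
    out <- data.frame(feature = nm,
                      mean_fld = mean(xv[yv == 1]), sd_fld = stats::sd(xv[yv == 1]),
                      mean_normal = mean(xv[yv == 0]), sd_normal = stats::sd(xv[yv == 0]),
                      statistic = NA_real_, p_value = NA_real_,
                      significant = FALSE, tested = FALSE)
    if (sum(obs) < min_obs) return(out)
    if (nm == "sex" || length(unique(xv)) == 2) {
      tab <- table(xv, yv)
    } else {
      breaks <- unique(stats::quantile(xv, probs = 0:4 / 4))
      if (length(breaks) < 3) return(out)   # nearly constant: untestable
      bins <- cut(xv, breaks, include.lowest = TRUE)
      tab <- table(bins, yv)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2) return(out)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out$statistic <- unname(ct$statistic)
    out$p_value <- ct$p.value
    out$significant <- is.finite(ct$p.value) && ct$p.value <= alpha
    out$tested <- TRUE
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
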