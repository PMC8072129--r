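# Group-median imputation: missing exam values are filled with the training
# median of the patient's (age-bin x sex) group. Analyte distributions shift
# with age and sex, so group medians are markedly better centres than a
# global median. Fallback chain for empty groups: sex median, then global
# median, making the filled table complete for every usable feature.

#' Fit a group-median imputation plan on training data
#'
#' Medians are computed over observed training values only, per
#' (age-bin, sex, feature), with sex-level and global medians as fallbacks.
#' Features with no observed training value are flagged unusable and left
#' untouched by [apply_imputer()].
#'
#' @param train Training cohort data frame (with `sex`, `age`).
#' @param binning A fitted [fit_chimerge()] scheme for age.
#' @param features Feature columns to cover (default: all).
#' @return An object of class `imputation_plan`.
#' @export
fit_imputer <- function(train, binning, features = feature_columns(train)) {
  if (nrow(train) == 0) stop("training table is empty")
  bins <- assign_bin(binning, train$age)
  key <- paste(bins, train$sex, sep = ":")
  plan <- list(binning = binning, features = features,
               group = list(), by_sex = list(), global = list(),
               unusable = character())
  for (f in features) {
    x <- train[[f]]
    obs <- !is.na(x)
    if (!any(obs)) {
      plan$unusable <- c(plan$unusable, f)
      next
    }
    g <- tapply(x[obs], key[obs], stats::median)
    plan$group[[f]] <- g
    plan$by_sex[[f]] <- tapply(x[obs], as.character(train$sex)[obs], stats::median)
    plan$global[[f]] <- stats::median(x[obs])
  }
  structure(plan, class = "imputation_plan")
}

#' Fill missing values using a fitted plan
#'
#' Every missing cell is filled with the first available of: the
#' (age-bin, sex) training median, the sex-level training median, the global
#' training median. Observed cells are untouched; the operation is
#' idempotent and never recomputes statistics from the table it fills
#' (no train/test leakage).
#'
#' @param plan An [fit_imputer()] plan.
#' @param table Cohort data frame to fill; its feature columns must be
#'   covered by the plan.
#' @return The table with all usable features complete.
#' @export
apply_imputer <- function(plan, table) {
  feats <- feature_columns(table)
  unknown <- setdiff(feats, plan$features)
  if (length(unknown) > 0)
    stop("features absent from the imputation plan: ", paste(unknown, collapse = ", "))
  bins <- assign_bin(plan$binning, table$age)
  key <- paste(bins, table$sex, sep = ":")
  for (f in setdiff(feats, plan$unusable)) {
    x <- table[[f]]
    miss <- is.na(x)
    if (!any(miss)) next
    fill <- unname(plan$group[[f]][key[miss]])
    sx <- as.character(table$sex[miss])
    need <- is.na(fill)
    if (any(need)) fill[need] <- unname(plan$by_sex[[f]][sx[need]])
    need <- is.na(fill)
    if (any(need)) fill[need] <- plan$global[[f]]
    x[miss] <- fill
    table[[f]] <- x
  }
  table
}

#' Serialize / restore an imputation plan as JSON
#'
#' @param plan An `imputation_plan`.
#' @param path File path.
#' @return `read_imputation_json` returns the `imputation_plan`.
#' @export
write_imputation_json <- function(plan, path) {
  x <- list(binning = unclass(plan$binning),
            features = plan$features,
            group = lapply(plan$group, as.list),
            by_sex = lapply(plan$by_sex, as.list),
            global = plan$global,
            unusable = plan$unusable)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imputation_json
#' @export
read_imputation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  plan <- list(
    binning = structure(list(cuts = as.numeric(unlist(x$binning$cuts)),
                             n_bins = x$binning$n_bins,
                             target_bins = x$binning$target_bins,
                             n_merges = x$binning$n_merges),
                        class = "chimerge_scheme"),
    features = as.character(unlist(x$features)),
    group = lapply(x$group, function(g) unlist(g)),
    by_sex = lapply(x$by_sex, function(g) unlist(g)),
    global = lapply(x$global, function(v) as.numeric(v)),
    unusable = as.character(unlist(x$unusable))
  )
  structure(plan, class = "imputation_plan")
}
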