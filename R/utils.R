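#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a per-stage seed from a global seed; stays inside 32-bit range.
stage_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) + 7919 * offset) %% (.Machine$integer.max - 1L)) + 1L
}

#' Columns of a cohort table that are exam features
#'
#' Everything except the bookkeeping columns `sex`, `age` and the label `fld`.
#'
#' @param table A cohort data frame.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("sex", "age", "fld"))
}

#' Write / read a cohort table as CSV
#'
#' Missing values are encoded as empty fields; columns are `sex` (0/1), `age`,
#' `fld` (0/1/empty = no ultrasound record), then the exam features.
#'
#' @param table A cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(table, path) {
  # %.17g round-trips doubles exactly; write.csv alone would truncate
  out <- as.data.frame(lapply(table, function(x)
    ifelse(is.na(x), "", sprintf("%.17g", x))), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, na.strings = c("", "NA"), check.names = FALSE)
  for (nm in names(tab)) tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}
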