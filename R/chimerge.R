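# ChiMerge: bottom-up supervised discretization. Bins start as the sorted
# distinct values; the adjacent pair whose 2x2 (bin x class) chi-square
# statistic is smallest — i.e. whose class distributions look most alike — is
# merged until the requested number of bins remains.

#' Chi-square statistic of two adjacent bins
#'
#' For a 2 (bins) x 2 (classes) count table, computes
#' `sum((A - E)^2 / E)` with expected counts `E = rowSums %o% colSums / N`.
#' Cells with zero expected count contribute 0, so a fully empty bin always
#' merges first.
#'
#' @param counts A 2x2 numeric matrix of non-negative counts, rows = the two
#'   adjacent bins, columns = the two classes.
#' @return The statistic (>= 0); 0 when the bins have proportional class
#'   counts or a margin is empty.
#' @export
chi_square_adjacent <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) return(0)
  e <- outer(rowSums(counts), colSums(counts)) / n
  sum(ifelse(e > 0, (counts - e)^2 / e, 0))
}

#' Fit a ChiMerge binning scheme
#'
#' Initializes one bin per distinct value (sorted), then repeatedly merges the
#' adjacent pair with the smallest chi-square statistic against the binary
#' label (leftmost pair on ties) until `min(target_bins, #distinct)` bins
#' remain. Intervals are right-closed with unbounded outer edges, so any
#' finite value — including unseen extremes — maps to a bin.
#'
#' @param values Numeric vector (e.g. ages). `NA` pairs are dropped.
#' @param labels Binary 0/1 vector of the same length.
#' @param target_bins Requested number of bins (default 5).
#' @return An object of class `chimerge_scheme` with elements `cuts`
#'   (ordered interior cut points, upper edges of all but the last bin),
#'   `n_bins`, `target_bins` and `n_merges`.
#' @export
fit_chimerge <- function(values, labels, target_bins = 5L) {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(values) == 0) stop("cannot fit a binning on empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (target_bins < 1) stop("target_bins must be >= 1")
  v <- sort(unique(values))
  counts <- cbind(
    as.vector(table(factor(values[labels == 0], levels = v))),
    as.vector(table(factor(values[labels == 1], levels = v)))
  )
  uppers <- v
  k0 <- length(v)
  goal <- min(target_bins, k0)
  while (nrow(counts) > goal) {
    k <- nrow(counts)
    chis <- vapply(seq_len(k - 1), function(i)
      chi_square_adjacent(counts[i:(i + 1), , drop = FALSE]), 0)
    j <- which.min(chis)                     # leftmost minimum
    counts[j, ] <- counts[j, ] + counts[j + 1, ]
    uppers[j] <- uppers[j + 1]
    counts <- counts[-(j + 1), , drop = FALSE]
    uppers <- uppers[-(j + 1)]
  }
  structure(list(cuts = uppers[-length(uppers)],
                 n_bins = nrow(counts),
                 target_bins = as.integer(target_bins),
                 n_merges = k0 - nrow(counts)),
            class = "chimerge_scheme")
}

#' @export
print.chimerge_scheme <- function(x, ...) {
  edges <- c(-Inf, x$cuts, Inf)
  iv <- paste0("(", edges[-length(edges)], ", ", edges[-1], "]")
  cat("ChiMerge binning scheme:", x$n_bins, "bins\n ", paste(iv, collapse = " "),
      "\n  (", x$n_merges, "merges )\n")
  invisible(x)
}

#' Map values to bins of a fitted scheme
#'
#' Intervals are right-closed: with cuts `c1 < ... < c_{k-1}`, bin 1 is
#' `(-Inf, c1]`, bin i is `(c_{i-1}, c_i]`, bin k is `(c_{k-1}, Inf)`.
#'
#' @param scheme A `chimerge_scheme`.
#' @param values Finite numeric vector.
#' @return Integer bin indices in `1..n_bins`.
#' @export
assign_bin <- function(scheme, values) {
  if (any(!is.finite(values))) stop("values must be finite")
  findInterval(values, scheme$cuts, left.open = TRUE) + 1L
}

#' Serialize / restore a binning scheme as JSON
#'
#' @param scheme A `chimerge_scheme`.
#' @param path File path.
#' @return `read_scheme_json` returns the `chimerge_scheme`.
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cuts <- as.numeric(x$cuts)
  structure(x, class = "chimerge_scheme")
}
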