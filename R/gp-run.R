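# Genetic-programming search for composite screening features. Fitness is
# the absolute Spearman rank correlation between a candidate expression's
# values and the ultrasound label; selection is truncation with elitism,
# offspring come from subtree crossover and mutation.

#' Genetic-programming configuration
#'
#' Defaults follow standard practice for this search: 1,000 individuals per
#' generation, 10 generations, tree depth at most 3 (up to 8 leaves), the
#' top 3 features kept.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of evolution steps (0 = score the random
#'   initial population only).
#' @param max_depth Tree depth bound in edges.
#' @param top_k Number of distinct best features returned.
#' @param crossover_rate Probability an offspring is produced by crossover
#'   (otherwise it is a copy of its first parent).
#' @param mutation_rate Probability an offspring is additionally mutated.
#' @param elite_fraction Fraction of the population copied unchanged into the
#'   next generation (at least one individual), making the best fitness
#'   non-decreasing across generations.
#' @param seed Integer seed; runs are fully reproducible.
#' @return A list of class `gp_config`.
#' @export
gp_config <- function(population_size = 1000L,
                      generations = 10L,
                      max_depth = 3L,
                      top_k = 3L,
                      crossover_rate = 0.8,
                      mutation_rate = 0.2,
                      elite_fraction = 0.05,
                      seed = 1L) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (top_k > population_size) stop("top_k cannot exceed population_size")
  rates <- c(crossover_rate, mutation_rate, elite_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 max_depth = as.integer(max_depth),
                 top_k = as.integer(top_k),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction,
                 seed = as.integer(seed)),
            class = "gp_config")
}

#' Spearman fitness of a candidate feature
#'
#' Absolute Spearman rank correlation (average ranks on ties) between the
#' feature values and the binary label; in \[0,1\] and invariant to strictly
#' monotone transforms of the values. Constant values score 0.
#'
#' @param values Numeric vector.
#' @param labels Binary 0/1 vector of the same length (not all equal).
#' @return Fitness in \[0,1\].
#' @export
spearman_fitness <- function(values, labels) {
  if (length(values) != length(labels)) stop("values and labels differ in length")
  if (length(values) < 3) stop("need at least 3 observations")
  if (length(unique(labels)) < 2) stop("labels must not be all equal")
  if (anyNA(values) || stats::sd(values) == 0) return(0)
  rho <- suppressWarnings(stats::cor(values, labels, method = "spearman"))
  if (is.na(rho)) 0 else abs(rho)
}

#' Min-max normalization fitted on training data
#'
#' Each selected column is scaled to \[0,1\] using the training minimum and
#' maximum; values outside the training range (e.g. in a test split) are
#' clipped; constant training columns map to 0.
#'
#' @param train Training cohort data frame (defines min/max).
#' @param apply_to Table to transform (default: the training table itself).
#' @param features Columns to scale (default: all feature columns plus
#'   `age`).
#' @return `apply_to` with the selected columns scaled.
#' @export
normalize_features <- function(train, apply_to = train,
                               features = c(feature_columns(train), "age")) {
  for (f in features) {
    lo <- min(train[[f]], na.rm = TRUE)
    hi <- max(train[[f]], na.rm = TRUE)
    x <- apply_to[[f]]
    if (hi > lo) {
      x <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
    } else {
      x <- ifelse(is.na(x), NA_real_, 0)
    }
    apply_to[[f]] <- x
  }
  apply_to
}

#' Evolve composite features by genetic programming
#'
#' Runs the evolutionary loop: score the population by Spearman fitness, copy
#' the elite, refill with rank-weighted parents recombined by subtree
#' crossover and mutation, repeat, and return the `top_k` best individuals
#' with pairwise distinct canonical expressions. Expect the table to be
#' imputed (complete) and min-max normalized — `log` and the protected
#' operators are calibrated for the \[0,1\] scale.
#'
#' @param table Data frame of predictor columns (no label column needed; if
#'   `fld` is present it is excluded from the leaf set).
#' @param labels Binary 0/1 vector, one per row.
#' @param config A [gp_config()].
#' @param features Candidate leaf names (default: all columns except `fld`).
#' @param keep_populations Keep every generation's population in the result
#'   (for diagnostics; memory grows with `generations`).
#' @return An object of class `gp_result`: `features` (list of
#'   `symbolic_feature`s, fitness-descending), `history` (best fitness per
#'   generation, element 1 = initial population), `no_signal` flag, `config`,
#'   and optionally `populations`.
#' @export
run_gp <- function(table, labels, config = gp_config(),
                   features = setdiff(names(table), "fld"),
                   keep_populations = FALSE) {
  if (length(labels) != nrow(table)) stop("labels must match table rows")
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  if (length(features) == 0) stop("no candidate features")
  ry <- rank(labels)
  cache <- new.env(parent = emptyenv())
  score <- function(tree) {
    key <- format_tree(tree)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- evaluate_tree(tree, table)
    f <- if (anyNA(v) || stats::sd(v) == 0) 0 else {
      rho <- stats::cor(rank(v), ry)        # Spearman via Pearson on ranks
      if (is.na(rho)) 0 else abs(rho)
    }
    cache[[key]] <- f
    f
  }
  P <- config$population_size
  withr::with_seed(config$seed, {
    pop <- replicate(P, random_tree(features, config$max_depth), simplify = FALSE)
    fits <- vapply(pop, score, 0)
    history <- max(fits)
    populations <- if (keep_populations) list(pop) else NULL
    n_elite <- max(1L, ceiling(config$elite_fraction * P))
    for (g in seq_len(config$generations)) {
      ord <- order(fits, decreasing = TRUE)
      w <- rev(seq_len(P))                   # rank-proportional parent weights
      newpop <- pop[ord[seq_len(n_elite)]]
      while (length(newpop) < P) {
        p1 <- pop[[ord[sample.int(P, 1, prob = w)]]]
        child <- if (stats::runif(1) < config$crossover_rate) {
          p2 <- pop[[ord[sample.int(P, 1, prob = w)]]]
          crossover(p1, p2, config$max_depth)
        } else p1
        if (stats::runif(1) < config$mutation_rate)
          child <- mutate(child, features, config$max_depth)
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fits <- vapply(pop, score, 0)
      history <- c(history, max(fits))
      if (keep_populations) populations[[g + 1L]] <- pop
    }
    ord <- order(fits, decreasing = TRUE)
    exprs <- vapply(pop, format_tree, "")
    top <- list()
    seen <- character()
    for (i in ord) {
      if (exprs[i] %in% seen) next
      seen <- c(seen, exprs[i])
      top[[length(top) + 1L]] <- structure(
        list(tree = pop[[i]], expression = exprs[i], fitness = fits[i]),
        class = "symbolic_feature")
      if (length(top) == config$top_k) break
    }
    no_signal <- max(fits) <= .Machine$double.eps
    if (no_signal)
      warning("no signal: every evolved feature has zero Spearman fitness")
    structure(list(features = top, history = history, no_signal = no_signal,
                   config = config, populations = populations),
              class = "gp_result")
  })
}

#' @export
print.gp_result <- function(x, ...) {
  cat("Genetic-programming feature search:", length(x$history) - 1,
      "generations, best fitness", sprintf("%.4f", max(x$history)), "\n")
  for (i in seq_along(x$features))
    cat(sprintf("  GA_fea%d = %s   (fitness %.4f)\n", i,
                x$features[[i]]$expression, x$features[[i]]$fitness))
  invisible(x)
}

#' Append evolved features to a table
#'
#' Evaluates each returned symbolic feature on `table` and binds the results
#' as new columns `GA_fea1`, `GA_fea2`, ...
#'
#' @param table A complete (imputed, normalized) cohort table.
#' @param gp A `gp_result` (or list of `symbolic_feature`s).
#' @return The table with the appended columns.
#' @export
append_gp_features <- function(table, gp) {
  feats <- if (inherits(gp, "gp_result")) gp$features else gp
  for (i in seq_along(feats))
    table[[paste0("GA_fea", i)]] <- evaluate_tree(feats[[i]]$tree, table)
  table
}

#' Serialize / restore symbolic features as JSON
#'
#' @param gp A `gp_result` or list of `symbolic_feature`s.
#' @param path File path.
#' @return `read_gp_features_json` returns a list of `symbolic_feature`s.
#' @export
write_gp_features_json <- function(gp, path) {
  feats <- if (inherits(gp, "gp_result")) gp$features else gp
  x <- lapply(feats, function(f)
    list(expression = f$expression, fitness = f$fitness))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gp_features_json
#' @export
read_gp_features_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(f) structure(
    list(tree = parse_expression(f$expression),
         expression = f$expression, fitness = as.numeric(f$fitness)),
    class = "symbolic_feature"))
}
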