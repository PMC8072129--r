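# Independent oracles, deliberately re-derived from first principles rather
# than sharing any code with the implementation they check.

# Exhaustive greedy ChiMerge: one bin per distinct sorted value; every step
# recomputes ALL adjacent chi-square statistics from the raw (value, label)
# pairs and merges the leftmost minimal pair. Returns the interior cut points.
oracle_chimerge_cuts <- function(values, labels, target_bins) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  v <- sort(unique(values))
  # bins as lists of member values
  bins <- lapply(v, function(x) x)
  chisq_of <- function(members_a, members_b) {
    a0 <- sum(labels == 0 & values %in% members_a)
    a1 <- sum(labels == 1 & values %in% members_a)
    b0 <- sum(labels == 0 & values %in% members_b)
    b1 <- sum(labels == 1 & values %in% members_b)
    m <- matrix(c(a0, b0, a1, b1), 2, 2)
    n <- sum(m)
    if (n == 0) return(0)
    e <- outer(rowSums(m), colSums(m)) / n
    s <- 0
    for (i in 1:2) for (j in 1:2)
      if (e[i, j] > 0) s <- s + (m[i, j] - e[i, j])^2 / e[i, j]
    s
  }
  while (length(bins) > min(target_bins, length(v))) {
    chis <- sapply(seq_len(length(bins) - 1), function(i)
      chisq_of(bins[[i]], bins[[i + 1]]))
    j <- which(chis == min(chis))[1]
    bins[[j]] <- c(bins[[j]], bins[[j + 1]])
    bins[[j + 1]] <- NULL
  }
  uppers <- sapply(bins, max)
  uppers[-length(uppers)]
}

# Spearman by the definitional route: average ranks computed by counting,
# then the Pearson product-moment formula, no calls to rank() or cor().
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) return(NA_real_)
  num / den
}

# AUC by exhaustive enumeration of all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Small deterministic labeled cohort fixture with controllable missingness.
make_fixture_cohort <- function(n = 200, seed = 42) {
  withr::with_seed(seed, {
    sex <- rbinom(n, 1, 0.5)
    age <- sample(20:80, n, replace = TRUE)
    TG <- exp(rnorm(n, log(1.4), 0.4))
    ALT <- exp(rnorm(n, log(22), 0.5))
    fld <- rbinom(n, 1, plogis(-1.2 + 1.2 * scale(TG)[, 1] + 0.8 * scale(log(ALT))[, 1]))
    data.frame(sex = sex, age = age, fld = fld, TG = TG, ALT = ALT)
  })
}
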