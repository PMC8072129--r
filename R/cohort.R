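# Synthetic physical-examination cohort generator.
#
# The generator emulates the statistical structure a screening pipeline for
# fatty liver disease (FLD) has to cope with in real electronic examination
# records: a ~23% ultrasound-confirmed prevalence, liver-panel analytes whose
# location depends on sex and age, a label driven nonlinearly by a composite
# of triglycerides and log-transaminase, pure-noise columns, and per-column
# missingness including near-empty columns.

.FLD_MARKERS <- c("TG", "ALT", "AST", "GGT", "UA", "GLU")

#' Configuration for the synthetic cohort generator
#'
#' @param n_samples Number of patients to simulate.
#' @param prevalence_target Target fraction of FLD-positive patients among the
#'   labeled rows, strictly inside (0,1). Default 0.23, the prevalence typical
#'   of adult examination cohorts in China.
#' @param male_fraction Fraction of male patients (sex = 1).
#' @param age_range Numeric length-2, minimum and maximum age in years.
#' @param n_informative How many of the named analytes (TG, ALT, AST, GGT, UA,
#'   GLU, in that order) to include; at most 6.
#' @param n_noise Number of pure-noise analyte columns, independent of the
#'   label.
#' @param effect_sizes Named coefficients of the latent risk score on
#'   standardized terms: `TG`, `logALT`, `GGT`, `GLU`, `age`. The label is
#'   Bernoulli(logistic(intercept + sum of terms)); the intercept is
#'   calibrated to `prevalence_target` by [calibrate_intercept()].
#' @param missing_rates Named per-column missingness fractions in \[0,1\] used
#'   by [inject_missingness()]. `NULL` builds the default: 0.08 on informative
#'   columns, 0.15 on noise columns, with the last `n_sparse_columns` noise
#'   columns at `sparse_rate`.
#' @param n_sparse_columns Number of near-empty columns (emulating exam items
#'   most patients never had).
#' @param sparse_rate Missingness rate of the sparse columns (>= 0.9).
#' @param unlabeled_fraction Fraction of rows with no ultrasound record
#'   (label absent).
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   table bit-identically.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 10000L,
                          prevalence_target = 0.23,
                          male_fraction = 0.55,
                          age_range = c(1, 100),
                          n_informative = 6L,
                          n_noise = 24L,
                          effect_sizes = c(TG = 1.4, logALT = 1.1, GGT = 0.7,
                                           GLU = 0.5, age = 0.7),
                          missing_rates = NULL,
                          n_sparse_columns = 2L,
                          sparse_rate = 0.95,
                          unlabeled_fraction = 0.05,
                          seed = 1L) {
  if (n_samples < 1) stop("n_samples must be positive")
  if (!(prevalence_target > 0 && prevalence_target < 1))
    stop("prevalence_target must lie strictly inside (0, 1)")
  if (!(male_fraction > 0 && male_fraction < 1))
    stop("male_fraction must lie strictly inside (0, 1)")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be (min, max) with min < max")
  if (n_informative < 1 || n_informative > length(.FLD_MARKERS))
    stop("n_informative must be between 1 and ", length(.FLD_MARKERS))
  if (any(!is.finite(effect_sizes)))
    stop("effect sizes must all be finite")
  if (n_sparse_columns > n_noise)
    stop("n_sparse_columns cannot exceed n_noise")
  informative <- .FLD_MARKERS[seq_len(n_informative)]
  noise <- if (n_noise > 0) sprintf("noise%02d", seq_len(n_noise)) else character()
  if (is.null(missing_rates)) {
    missing_rates <- c(
      stats::setNames(rep(0.08, length(informative)), informative),
      stats::setNames(rep(0.15, length(noise)), noise)
    )
    if (n_sparse_columns > 0)
      missing_rates[utils::tail(noise, n_sparse_columns)] <- sparse_rate
  }
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing rates must lie in [0, 1]")
  structure(list(
    n_samples = as.integer(n_samples),
    prevalence_target = prevalence_target,
    male_fraction = male_fraction,
    age_range = age_range,
    informative = informative,
    noise = noise,
    effect_sizes = effect_sizes,
    missing_rates = missing_rates,
    n_sparse_columns = as.integer(n_sparse_columns),
    unlabeled_fraction = unlabeled_fraction,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Draw sex, age and the full analyte panel plus the latent (intercept-free)
# risk score for n patients. Shared by generate_cohort() and the intercept
# calibration so both see the same generative law.
.simulate_predictors <- function(config, n, seed) {
  withr::with_seed(seed, {
    sex <- stats::rbinom(n, 1, config$male_fraction)
    # bimodal exam-cohort age structure: working-age and retirement peaks
    young <- stats::runif(n) < 0.55
    age <- ifelse(young, stats::rnorm(n, 38, 13), stats::rnorm(n, 58, 14))
    age <- round(age)
    lo <- config$age_range[1]; hi <- config$age_range[2]
    out <- age < lo | age > hi
    while (any(out)) {   # resample outside the truncation window
      m <- sum(out)
      yg <- stats::runif(m) < 0.55
      age[out] <- round(ifelse(yg, stats::rnorm(m, 38, 13), stats::rnorm(m, 58, 14)))
      out <- age < lo | age > hi
    }
    a <- age - 45
    # log-normal analytes with sex- and age-dependent locations
    # (physiologically plausible units: TG/GLU mmol/L, enzymes U/L, UA umol/L)
    locTG <- log(1.30) + 0.18 * sex + 0.006 * a
    TG <- exp(locTG + stats::rnorm(n, 0, 0.42))
    locALT <- log(20) + 0.30 * sex + 0.002 * a
    ALT <- exp(locALT + stats::rnorm(n, 0, 0.50))
    # AST tracks ALT, UA tracks TG (shared hepatic / metabolic physiology)
    AST <- exp(log(22) + 0.10 * sex + 0.001 * a +
                 0.55 * (log(ALT) - locALT) + stats::rnorm(n, 0, 0.25))
    GGT <- exp(log(25) + 0.45 * sex + 0.004 * a + stats::rnorm(n, 0, 0.55))
    UA <- exp(log(310) + 0.22 * sex + 0.0015 * a +
                0.30 * (log(TG) - locTG) + stats::rnorm(n, 0, 0.16))
    GLU <- exp(log(5.0) + 0.05 * sex + 0.004 * a + stats::rnorm(n, 0, 0.15))
    panel <- data.frame(TG = TG, ALT = ALT, AST = AST, GGT = GGT,
                        UA = UA, GLU = GLU)[config$informative]
    z <- function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    terms <- cbind(TG = z(TG), logALT = z(log(ALT)), GGT = z(GGT),
                   GLU = z(GLU), age = z(age))
    beta <- config$effect_sizes[colnames(terms)]
    beta[is.na(beta)] <- 0
    eta <- drop(terms %*% beta)
    noise <- lapply(seq_along(config$noise), function(j) {
      exp(stats::rnorm(n, log(5) + 0.10 * (j - 1), 0.30 + 0.01 * j))
    })
    names(noise) <- config$noise
    features <- cbind(panel, as.data.frame(noise))
    list(sex = sex, age = age, features = features, eta = eta)
  })
}

#' Calibrate the latent-score intercept to the target prevalence
#'
#' Finds the intercept `b0` such that `mean(plogis(b0 + eta))` over a large
#' simulated draw of the latent risk score `eta` equals the configured
#' prevalence target, by monotone 1-D root search.
#'
#' @param config A [cohort_config()].
#' @param n_cal Size of the calibration draw.
#' @return The intercept (numeric scalar).
#' @export
calibrate_intercept <- function(config, n_cal = 50000L) {
  if (any(!is.finite(config$effect_sizes))) stop("effect sizes must be finite")
  sim <- .simulate_predictors(config, n_cal, stage_seed(config$seed, 1))
  f <- function(b0) mean(stats::plogis(b0 + sim$eta)) - config$prevalence_target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unreachable: latent score is degenerate")
  stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Generate a synthetic examination cohort
#'
#' Simulates `n_samples` patients under the configured generative model:
#' sex ~ Bernoulli(male_fraction); age from a truncated bimodal mixture;
#' log-normal analytes with sex/age-dependent locations; latent risk score
#' on standardized TG, log(ALT), GGT, GLU and age; label ~
#' Bernoulli(logistic(score)) with a fraction of rows left unlabeled
#' (no ultrasound record). The returned table is complete; use
#' [inject_missingness()] to mask values.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `sex`, `age`, `fld` and the features.
#' @export
generate_cohort <- function(config) {
  b0 <- calibrate_intercept(config)
  sim <- .simulate_predictors(config, config$n_samples, config$seed)
  withr::with_seed(stage_seed(config$seed, 3), {
    y <- stats::rbinom(config$n_samples, 1, stats::plogis(b0 + sim$eta))
    if (config$unlabeled_fraction > 0)
      y[stats::runif(config$n_samples) < config$unlabeled_fraction] <- NA_integer_
  })
  out <- cbind(data.frame(sex = sim$sex, age = sim$age, fld = y), sim$features)
  rownames(out) <- NULL
  out
}

#' Mask feature values completely at random
#'
#' Each feature column is masked independently at its configured rate
#' (`config$missing_rates`, matched by column name; unlisted columns are left
#' intact). `sex`, `age` and the label are never masked.
#'
#' @param table A cohort data frame.
#' @param config A [cohort_config()].
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, config) {
  rates <- config$missing_rates
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]")
  cols <- intersect(names(rates), feature_columns(table))
  withr::with_seed(stage_seed(config$seed, 4), {
    for (nm in cols) {
      r <- rates[[nm]]
      if (r > 0) table[[nm]][stats::runif(nrow(table)) < r] <- NA_real_
    }
  })
  table
}
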