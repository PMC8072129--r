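---
title: "Methods: screening for fatty liver disease from routine exam records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for fatty liver disease from routine exam records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fldscreen` builds a fatty liver disease (FLD) screening score from the kind
of table a hospital health database exports: one row per patient, routine
exam analytes as columns, `sex`, `age`, and a 0/1 ultrasound diagnosis that
is absent for patients who never had an ultrasound. This vignette explains
each modeling choice, what the synthetic cohort does and does not emulate,
and the numerical conventions the implementation fixes.

```{r setup}
library(fldscreen)
```

## The screening problem and the pipeline

FLD is highly prevalent (roughly a fifth to a quarter of adults), reversible
early, and diagnosed by imaging that is impractical for mass screening. The
pipeline turns already-collected exam panels into a ranking score: patients
scored high should be referred for ultrasound. Because the deployment metric
is the ability to *rank* (screening selects a top fraction), all evaluation
is by ROC AUC — the probability a random positive outranks a random
negative — which is prevalence-free and threshold-free.

Stages, in order: drop unlabeled patients, drop near-empty exam items,
stratified 70/30 split, ChiMerge age binning fitted on the training split,
(age-bin × sex) median imputation fitted on the training split, min-max
normalization fitted on the training split, genetic-programming (GP) feature
synthesis on the training split, gradient boosting, evaluation on the
held-out split. Everything fitted is fitted on training rows only; the test
split is transformed with trained parameters, never refitted — this
anti-leakage discipline matters most for the imputation medians and
normalization ranges.

## ChiMerge age binning

Analyte distributions shift with age, so the imputation groups need an age
partition. Equal-width or decade bins ignore the label; ChiMerge instead
merges adjacent age bins whose FLD prevalence is statistically
indistinguishable. Each candidate pair of adjacent bins forms a 2×2
contingency table against the label with statistic
$\chi^2 = \sum_{i}\sum_{j} (A_{ij}-E_{ij})^2/E_{ij}$; the pair with the
smallest statistic merges until the target count (default 5) remains.

Conventions the algorithm fixes (the classical formulation leaves them
open):

* initialization is one bin per distinct observed value;
* ties merge the *leftmost* minimal pair, making the fit deterministic;
* cells with zero expected count contribute 0, so empty bins merge first;
* stopping is by bin count only (no χ² significance threshold), matching a
  target of 5 groups;
* intervals are right-closed with unbounded outer edges, so any test-set
  age — including ages outside the training range — maps to a bin.

`fit_chimerge()` is checked against an independent exhaustive greedy oracle
that recomputes every adjacent statistic from the raw pairs at every step.

## Group-median imputation

Exam tables are missing-heavy: patients take different panels. Because
analyte medians differ strongly by sex and age group, missing cells are
filled with the *training* median of the patient's (age-bin × sex) group.
The fallback chain — group median, then sex median, then global median — is
a totality device: a group can be empty in training (e.g. no observed values
among young women for some analyte), and a pipeline stage must never emit
missing values downstream. Even-sized groups use the mid-mean of the two
central order statistics. Imputation is idempotent by construction, and
near-empty columns (dropped earlier at the 2/3 missing-fraction threshold)
never reach it.

The threshold for dropping sparse items is configurable
(`prep_config(max_missing_fraction=)`, with an absolute-count mode) because
source descriptions of this filtering step in the literature are often
ambiguous; 2/3 is the default.

## GP feature synthesis

Clinically, *combinations* of analytes (e.g. the AST/ALT ratio) carry
diagnostic signal that single items do not. The package searches the space
of operator trees over features — leaves are column names, inner nodes are
`+ − * / log sqrt`, depth at most 3 edges (up to 8 leaves) — for expressions
maximizing $|\rho_{Spearman}(\text{expression}, \text{label})|$. Spearman is
the right fitness for a tree-based downstream learner: it measures monotone
association, exactly what a decision-tree split can exploit, and is
invariant to the arbitrary monotone rescalings the trees apply.

Search settings: population 1,000, 10 generations, truncation selection with
a 5% elite copied unchanged (so the best fitness never decreases),
rank-weighted parent sampling, subtree crossover at rate 0.8 (retried up to
8 times when the child would exceed the depth bound, then the first parent
is returned), subtree mutation at rate 0.2 grown to the remaining depth
budget. The top 3 *distinct* canonical expressions are appended as
`GA_fea1..3`; distinctness is enforced on the expression strings so the
output is not three copies of one formula.

Numerical conventions: fitness is the absolute correlation (a tree's sign is
arbitrary — negating a tree flips ρ); evaluation runs on min-max normalized
[0,1] features, and operators are protected so it is total: `log(x)` means
`log(|x|)` with `log(0) = 0`, `sqrt(x)` means `sqrt(|x|)`, and `x/y`
returns 1 when `|y| < 1e-12`. Constant expressions score fitness 0. No
parsimony penalty or constant terminals are used. Unary operators count
toward the depth budget like binary ones; this is one of several readings of
a "depth ≤ 3 binary tree" and was chosen for a uniform, checkable bound.

## The classifier and its evaluation

The boosted-tree learner is deliberately delegated to XGBoost rather than
reimplemented — it is a commodity component; what the pipeline depends on is
its contract: per-row scores, per-feature split counts, and determinism
under a fixed seed with single-threaded training. The defaults
(`classifier_config()`) are a fixed operating point: depth-3 trees,
learning rate 0.07, 150 rounds, positive class upweighted 2×, and mild
regularization. Rather than an automated hyperparameter search the package
provides a plain stratified 3-fold CV harness (`cv_auc()`) for manual
exploration.

Evaluation artifacts:

* **AUC** — rank-based Mann–Whitney with ties counted ½, checked against an
  exhaustive pair-enumeration oracle;
* **learning curve** — train/test AUC over a boosting-round grid, the
  bias–variance diagnostic (train AUC rises with capacity; a widening gap is
  overfitting);
* **importance** — split counts ("weight"-style), *not* gain: the number of
  times a feature is chosen to split, summing to the ensemble's total
  splits; ties are broken alphabetically for a stable ranking;
* **incremental feature curve** — the model retrained on the top-m features
  only, showing how few items a deployable screener needs;
* **false-negative profile** — per-feature means/SDs of missed positives
  versus all positives; missed FLD patients tend to be those whose exam
  indicators look normal, an honest limit of any indicator-based screener.
  The profiling threshold defaults to 0.5 (AUC itself needs none).

## The synthetic cohort: what it emulates, and what it does not

Real screening cohorts are protected; the generator
(`cohort_config()` / `generate_cohort()`) reproduces the *structure* the
pipeline's stages rely on, with every default configurable:

* ~23% labeled prevalence, hit by calibrating the logistic intercept with a
  1-D root search on a 50,000-draw simulation of the latent score;
* a bimodal age mixture (working-age and retirement peaks, truncated to
  1–100 years, integer-rounded as exam records are);
* log-normal analytes with sex- and age-dependent locations at
  physiologically plausible scales (TG ≈ 1.3 mmol/L, ALT ≈ 20 U/L, GGT ≈ 25
  U/L, …), with AST correlated to ALT and UA to TG as in real physiology, so
  the class-separation pattern across TG/ALT/AST/GGT/UA/GLU/age resembles
  published cohort summaries;
* a label depending *nonlinearly* (through log ALT) on a feature composite,
  so GP synthesis has genuine signal to recover;
* pure-noise columns, two near-empty columns (95% missing), 5% unlabeled
  rows, and per-column missing-completely-at-random masking.

Effect sizes default to `c(TG=1.4, logALT=1.1, GGT=0.7, GLU=0.5, age=0.7)`
on standardized terms, chosen once so the latent score's Bayes AUC is ≈0.91
— the discrimination regime of published FLD screeners, leaving a fitted
model in the high-0.8s. Missingness is MCAR because it is the weakest
mechanism consistent with median imputation; real exam missingness is partly
informative (who gets which panel is not random), and nothing here emulates
that. The generator also does not reproduce any real cohort's exact moments,
correlation matrix, or 129-item breadth (default 30 columns): passing tests
show the *method* behaves correctly on data with this structure, not that
the synthetic numbers transfer to any particular hospital.

## Determinism and problem sizes

A single global seed derives per-stage seeds, so `run_pipeline()` is
bit-reproducible including its JSON artifacts, and each stage can be re-run
in isolation from the previous stage's artifacts. The package's own test
suite exercises the full defaults (10,000-patient cohorts, GP population
1,000 × 10 generations) for the end-to-end properties, and smaller
fixtures (hundreds of rows, GP populations of ~100) for unit behavior —
sizes at which every property that should hold asymptotically already holds
comfortably.

Known limitations: MCAR missingness only; no multiple-testing correction in
the class summary (it mirrors descriptive-table practice, not confirmatory
inference); no calibration of the score's probabilities (ranking only); the
GP returns expressions, not causal claims — a high-fitness composite is a
screening feature, nothing more.
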