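# fldscreen

Non-invasive screening for fatty liver disease (FLD) from routine physical
examination records. Ultrasound, CT and biopsy diagnose FLD reliably but are
too invasive or costly for population-scale screening; routine exam panels
(blood lipids, liver enzymes, glucose, uric acid) are already collected for
millions of patients. `fldscreen` implements a complete, reproducible
machine-learning pipeline that turns such a table into a screening score, and
ships a seeded synthetic cohort generator so every stage can be developed and
tested without access to protected patient data.

The package is aimed at biostatisticians and epidemiologists building or
auditing tabular EHR risk models.

## The method

Given a samples × features table with `sex`, `age`, a binary ultrasound label
`fld`, and numeric exam items with missing values, the pipeline runs:

1. **Filtering** — drop patients with no ultrasound record; drop exam items
   whose missing fraction exceeds 2/3; stratified 70/30 train/test split.
2. **ChiMerge age binning** — supervised bottom-up discretization of age
   against the label. Starting from one bin per distinct age, the adjacent
   pair with the smallest chi-square independence statistic

   χ² = Σᵢ Σⱼ (Aᵢⱼ − Eᵢⱼ)² / Eᵢⱼ,  Eᵢⱼ = Rᵢ·Cⱼ / N

   is merged (leftmost on ties) until 5 right-closed bins remain.
3. **Group-median imputation** — each missing cell is filled with the
   training median of its (age-bin × sex) group, falling back to the sex
   median and then the global median when a group was never observed.
4. **Genetic-programming feature synthesis** — evolutionary search over
   expression trees (leaves = features; operators `+ − * / log sqrt`;
   depth ≤ 3) with fitness |ρ_Spearman(feature, label)|, population 1,000,
   10 generations, elitist truncation selection, subtree crossover and
   mutation. The top three distinct expressions are appended as
   `GA_fea1..3`. Operators are protected (`log(0)=0`, `log|x|`, `√|x|`,
   `x/y = 1` for |y| < 1e−12) so evaluation is total on the min-max
   normalized [0,1] feature scale.
5. **Gradient boosting** — an XGBoost `binary:logistic` model with the fixed
   operating point `max_depth 3, learning_rate 0.07, n_estimators 150,
   scale_pos_weight 2, min_child_weight 6, gamma 0.2, reg_alpha 0.1`.
6. **Evaluation** — rank-based (Mann–Whitney) ROC AUC with ties counted ½,
   train/test learning curves over boosting rounds, split-count feature
   importance, incremental top-m feature curves, and a profile of the
   false-negative patients.

The synthetic generator draws sex, a bimodal age mixture, and log-normal
analytes (TG, ALT, AST, GGT, UA, GLU) with sex/age-dependent locations; the
label is Bernoulli(logistic(η)) with η a linear score on standardized TG,
log(ALT), GGT, GLU and age, whose intercept is calibrated by root search to a
23% prevalence. Pure-noise columns, near-empty columns and unlabeled rows are
included so the filtering, imputation and importance stages all have real
work to do.

## Worked example

```r
library(fldscreen)
report <- run_pipeline(pipeline_config(seed = 1), verbose = TRUE)
print(report)
```

prints (abridged):

```
labeled rows: 9537; prevalence 0.230
dropped sparse columns: noise23, noise24
age bins: 5 (cuts 30, 42, 57, 73); merges: 93
GA_fea1 = ((GGT*TG)*(sqrt(age)*(ALT*TG)))  (fitness 0.5427)
GA_fea2 = log(((TG+ALT)+(GLU*age)))  (fitness 0.5417)
GA_fea3 = ((TG*age)*(sqrt(TG)*ALT))  (fitness 0.5392)
train AUC 0.9300 | test AUC 0.8935
```

Reading the output: of 10,000 simulated patients, 9,537 had an ultrasound
label and 23.0% were positive; the two near-empty columns were dropped;
ChiMerge found five age groups (cut points 30, 42, 57, 73 years after 93
merges); the GP evolved three composite features dominated by TG, ALT, GGT
and age — echoing clinically used composite indices — and the boosted model
reached a held-out AUC of 0.894, with the small train/test gap indicating no
overfitting at this operating point. `feature_importance(report$model)` shows
the evolved features and raw liver-panel analytes at the top of the split
count ranking.

A thin command-line wrapper is installed under
`inst/scripts/fld-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/fld-pipeline.R", package="fldscreen"))')" \
    --seed 1 --out artifacts/ --verbose
```

It writes the fitted binning scheme, imputation plan, GP features and the
evaluation report as JSON/CSV artifacts.

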