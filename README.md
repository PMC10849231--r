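# splitaudit

Auditing train/test performance bias for machine-learning classifiers on
limited case-control cohorts.

## Why

When a clinical cohort of a few hundred cases is split once into training
and test sets, both performance estimates are tied to the accident of that
split: the two arms are complementary samples of the same finite pool.
Repeating the split reveals the consequence — training and test AUC trade
off along an anti-diagonal (higher training AUC pairs with lower test AUC
and vice versa), and a single-split study can land anywhere on that band.
`splitaudit` provides the full audit for this phenomenon on any case-level
feature table, and a synthetic cohort generator with analytically known
discriminability so the whole pipeline is testable without patient data.

The core pieces:

* **Binormal-calibrated cohort generator** — class-conditional Gaussian
  features with equicorrelated covariance; the class separation `d` is set
  so the population AUC is exactly `pnorm(d / sqrt(2))`
  (`generate_cohort()`, `population_auc_from_separation()`).
* **Prevalence-balanced repeated shuffle-splits** with exact stratified
  allocation (round to nearest, ties down) and per-split Welch balance
  tests on nuisance covariates (`shuffle_split()`, `balance_check()`).
* **Repeated nested cross-validation** — per outer fold: per-vendor
  z-scoring fit on the outer-training portion, inner 3-fold grid search
  over the decade `C` grid `1e-10 … 1e10` (L2 logistic, compiled Newton
  path solver) or an SVM grid, optional stability feature selection; the
  most frequently selected configuration is frozen into one fixed model
  per split (`repeated_nested_cv()`, `modal_selection()`, `fit_final()`).
* **Evaluation** — midrank Mann–Whitney AUC (ties count one half), OLS
  train-vs-test tradeoff regression, paired sign-flip permutation model
  comparison (`auc()`, `tradeoff_analysis()`, `compare_models()`).
* **Incremental-cohort learning curves** — 20 nested chains grown in
  steps of 100 cases with a formal median-vs-IQR convergence rule
  (`nested_cohorts()`, `cv_at_sizes()`, `convergence_check()`).
* **One-call audit** — `run_audit()` drives cohort → splits → nested CV →
  fixed model → test AUC for every configured model and writes a
  byte-reproducible results bundle (CSV ledgers + JSON summary + config).

## Worked example

```r
library(splitaudit)

params <- generator_params(n_cases = 300, prevalence = 0.2, n_radiomic = 20,
                           n_clinical = 4, n_informative_radiomic = 8,
                           target_population_auc = 0.70, seed = 1)
cohort <- generate_cohort(params)
cohort
#> <cohort> 300 cases, 60 positive (20.0%), 24 features, vendors: Hologic/GE

cfg <- cv_config(n_repeats = 5, seed = 2)
splits <- shuffle_split(cohort, 180, n_splits = 20, master_seed = 3)
ledger <- do.call(rbind, lapply(splits, function(s) {
  cvo <- repeated_nested_cv(cohort, s$train_indices, cfg, features = "radiomics")
  model <- fit_final(cohort, s$train_indices, modal_selection(cvo), cfg,
                     features = "radiomics")
  data.frame(split_id = s$split_id,
             train_auc = cvo$mean_validation_auc,
             test_auc  = evaluate_split(model, cohort, s$test_indices))
}))
head(ledger, 3)
#>   split_id train_auc test_auc
#> 1        1     0.606    0.738
#> 2        2     0.687    0.642
#> 3        3     0.684    0.627

tradeoff_analysis(ledger)
#> <tradeoff> n = 20, slope = -1.034, r^2 = 0.667, pearson r = -0.817, p = 1.12e-05
```

Each ledger row is one random 180/120 split of the same 300-case pool:
`train_auc` is the repeated nested-CV estimate on the training arm,
`test_auc` the frozen model's AUC on the untouched complement. The
regression quantifies the anti-diagonal: a slope near −1 with strongly
negative Pearson r means splits that looked better in training
systematically tested worse — the performance bias this package audits.
For the full pipeline (multiple model definitions, balance flags, paired
comparisons, YAML configs) see `?run_audit` and the methods vignette in
`vignettes/performance-bias-audit.Rmd`.

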