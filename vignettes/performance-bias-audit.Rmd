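---
title: "Auditing train/test performance bias on limited cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing train/test performance bias on limited cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical machine-learning studies are routinely built on cohorts of a few
hundred cases. When such a cohort is split once into a training and a test
set, both performance estimates inherit the accident of that particular
split: the two arms are complementary samples of the *same* finite pool, so
a split that hands the "easier" cases to training leaves the harder ones
for testing. Across repeated random splits this produces an anti-diagonal
pattern — higher training AUC pairs with lower test AUC and vice versa —
and single-split studies can land anywhere on that band.

`splitaudit` packages the machinery needed to quantify this on any
case-level feature table: prevalence-balanced repeated shuffle-splits,
repeated nested cross-validation with modal hyperparameter selection, the
train-versus-test tradeoff regression, per-split covariate-balance
monitoring, and incremental-cohort learning curves. Because real clinical
tables are rarely shareable, the package ships a synthetic cohort
generator whose population discriminability is known in closed form, so
every stage of the pipeline is testable end to end.

## The synthetic cohort model

`generate_cohort()` draws class-conditional multivariate Gaussian features
with a shared equicorrelated covariance
$\Sigma = (1-\rho) I + \rho J$ (default $\rho = 0.3$). The positive-class
mean shift $\Delta$ is confined to an "informative" subset of features
(default 20 of 109 radiomic and 3 of 4 clinical) and scaled so that its
Mahalanobis norm equals $d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC}^*)$. Under
this binormal construction the best achievable (population) AUC is exactly
$\Phi(d/\sqrt 2) = \mathrm{AUC}^*$, and `oracle_scores()` — the projection
on the true discriminant $\Sigma^{-1}\Delta$ — attains it asymptotically.
That closed form is what the calibration tests check: the empirical
pair-counting AUC of the oracle score on $10^5$ draws must match
$\Phi(d/\sqrt 2)$ within $\pm 0.01$ for $d \in \{0.25, 0.5, 1, 1.5\}$.

Default study conditions mirror a single-institution screening cohort:
700 cases at 16.3% outcome prevalence (exactly 114 positives — the
positive count is `round(prevalence * n)` and is exact by construction),
two vendor strata assigned independently of the outcome, and two nuisance
covariates with class-specific normal models — age $N(62, 10^2)$ versus
$N(66, 10^2)$ years and lesion size $N(12, 6^2)$ versus $N(16, 8^2)$ mm
for the negative/positive classes. These covariate magnitudes are
stand-ins chosen so that per-split balance tests have occasional but not
overwhelming power; no distributional facts about the real features they
emulate are available, and none of the package's checks depend on their
specific values. Vendor strata differ by a location/scale offset applied
to all features (shift 0.5, scale 1.25 for the second stratum), which is
what makes *per-vendor* standardization consequential.

What the generator deliberately does **not** emulate: heavy-tailed or
skewed feature marginals, vendor-by-outcome confounding, missingness, and
label noise. Passing tests therefore demonstrate that the *estimation
machinery* behaves correctly under a clean, known model — not that any
particular clinical dataset is free of additional pathologies.

## The audited pipeline

For a pool of $n$ cases, `shuffle_split()` repeatedly permutes positives
and negatives separately and allocates
$\mathrm{train\_pos} = \mathrm{round}(n_\mathrm{pos} \cdot n_\mathrm{train}/n)$
positives to the training arm (round to nearest, exact ties down — the
convention that reproduces the 65/335 train and 49/251 test composition
of a 114/586 pool at $n_\mathrm{train} = 400$). Each split is seeded by a
documented counter scheme, so any split is re-creatable in isolation and
the whole sequence is byte-reproducible.

Training performance for one split is estimated by
`repeated_nested_cv()`: `n_repeats` times, the training arm is reshuffled
into `k_folds` stratified outer folds; per outer fold, features are
z-scored per vendor on the outer-training portion only, an inner 3-fold
grid search selects the inverse-penalty $C$ (decade grid
$10^{-10} \ldots 10^{10}$, 21 points) — and, in stability mode, the
feature-subset size — by inner validation AUC, and the refit outer model
is scored on the held-out fold. The average over all repeats is the
training AUC. `modal_selection()` then picks the most frequently winning
configuration across all inner-selection events (ties to the smaller $C$
or simpler kernel), `fit_final()` freezes one model on the full training
arm, and `evaluate_split()` scores the untouched test arm.

Choices made where the underlying design was open:

* **Inner selection.** The inner loop is a 3-fold stratified grid search
  (a conventional grid-search default that keeps inner folds large enough
  at desk-scale training sizes); granularity is one selection event per
  outer fold, so tallies count `k_folds * n_repeats` events.
* **Stability feature selection.** Implemented as frequency thresholding:
  each event ranks features by absolute two-sample $t$ statistic on its
  outer-training portion and tunes the retained count over
  `k_features_grid`; features selected in ≥ 50% of events (configurable)
  form the final subset. This is the most common reading of "stabilized"
  selection in radiomics, where no single canonical operator exists.
* **Standardization scope.** `train_only` by default (no test statistic
  influences any stored parameter — the leakage guard is tested);
  `whole_dataset` is available as an explicit mode. Population ($1/n$)
  variance is the default convention, sample variance a switch.
* **Balance monitoring.** Welch's two-sample $t$ per covariate at
  $\alpha = 0.05$, uncorrected — each split is flagged on its own, and
  under label-independent covariates the per-covariate flag rate is
  calibrated at $\alpha$ (tested over 1 000 splits).
* **Tradeoff inference.** OLS of test on train AUC with the two-sided
  slope $t$-test; model pairs are compared by a paired sign-flip
  permutation test on per-split test-AUC differences ($10^4$ flips,
  add-one $p$).
* **SVM scores.** Raw decision values feed the AUC; calibration is
  irrelevant to a rank statistic. For the SVM kind no tradeoff sign is
  asserted anywhere — its train/test scatter is genuinely less structured.

## Learning curves and the convergence rule

`nested_cohorts()` grows 20 random chains of sub-cohorts in steps of 100
cases without replacement, keeping the prevalence-preserving positive
count at every size; every chain terminates in the identical full pool.
`cv_at_sizes()` runs the repeated nested CV at each size and summarizes
quartiles across chains (type-7 linear interpolation, fixed for test
stability). Because the CV shuffling seed comes from the configuration
alone, the full-size point has *exactly* zero spread — a structural
feature, not an estimate.

"The median stopped changing" is formalized in `convergence_check()`: for
each consecutive size pair, $|\Delta\,\mathrm{median}|$ is compared with
the IQR at the larger size, and the curve converges at the smallest size
after which every pair satisfies the rule (if all pairs satisfy it, the
smallest evaluated size). The terminal pair is excluded when its larger
size has zero spread because every chain holds the identical full pool:
that IQR of exactly 0 is a degenerate design point, and retaining it
would force "never converged" for any nonzero median change, defeating
the rule's purpose.

## Numerical choices

The L2-penalized logistic objective
$\sum_i \log(1+e^{\eta_i}) - y_i \eta_i + \lVert w\rVert^2 / (2C)$
(intercept unpenalized) is minimized by a damped Newton method with
backtracking line search, warm-started along the ascending-$C$ path, to an
objective tolerance of $10^{-8}$; the objective trace is monotone by
construction and is tested against an independent generic optimizer. The
compiled path solver exists because one audit performs on the order of
$10^5$ fits. AUC uses the midrank Mann–Whitney form, which equals
exhaustive pair enumeration with ties counted one half (tested on random
tied instances). Degenerate inputs fail loudly with classed errors:
single-class labels, constant features within a vendor, unseen vendor
strata at scoring time, infeasible stratified allocations.

## Problem sizes used by the shipped checks

The package's own test battery and the results-reproduction script run at
desk scale, chosen once: the tradeoff experiment uses 100 shuffle-splits
of a 700-case pool (population AUC 0.70) with 5-fold × 10-repeat nested
CV; the learning curve uses 20 chains with 2-repeat CV; balance
calibration uses 1 000 splits; generator calibration uses $10^5$ draws.
The full 200-repeat design of a production audit is a configuration
value, not a code change.

## Known limitations

* The generator's Gaussian/equicorrelated model gives closed-form truth
  at the price of realism; effect sizes concentrated on a fixed leading
  subset of features are a simplification.
* `mean_validation_auc` estimates the performance of models trained on
  $(k-1)/k$ of the arm, evaluated within the arm; its between-arm
  variance is the phenomenon under study, so no variance estimate is
  attached to a single arm's value.
* The SVM path fits one model per grid point per inner fold and is
  intended for small designs; the logistic path is the workhorse.
* Paired model comparisons assume the same split sequence for both
  models, which `run_audit()` guarantees by construction.
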