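---
title: "Domain-wise random-forest prognosis with permutation inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-wise random-forest prognosis with permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rfcourse` implements a complete prognosis-modelling pipeline for
naturalistic psychiatric cohorts: two binary recovery outcomes (recovery
from anxiety disorders, recovery from all common mental disorders) are
predicted from several hundred mixed-type baseline items grouped into five
predictor domains, with random forests evaluated by matched-fold repeated
cross-validation and interrogated by permutation-based significance and
importance machinery. This vignette explains the models and procedures,
the tunable parameters, the synthetic-data design that the test suite
exercises, the numerical choices, and the limitations we have measured.

## The pipeline

1. **Cohort table.** Patients × items with three kinds of item
   (continuous, ordinal, nominal), a missingness state per cell, and a
   separate *applicability* state: a skip-pattern child item is "not
   applicable" (distinct from missing) whenever its parent item sits at a
   designated off level.
2. **Preparation.** Inapplicable cells are first recoded to out-of-support
   sentinels — 0 for continuous items (all observed continuous values are
   strictly positive) and an extra `NA_CATEGORY` level for categorical
   items — so the item remains usable for classification and the model can
   see "did not apply" as its own state. Then items with more than 20 % of
   patients missing are dropped, then patients missing more than 20 % of
   the retained items. Both thresholds are strict inequalities: exactly
   20 % is retained. The item filter runs first so that patient
   missingness is judged against the item set actually analyzed. If a
   retained item still exceeds 10 % missingness, the pipeline logs a
   warning rather than dropping it; with the default generator settings
   this warning fires, because item missingness rates are drawn uniformly
   up to 23 % and survivors of the 20 % filter can land between 10 % and
   20 %.
3. **Cross-validation.** `make_fold_plan()` builds a repeated stratified
   partition (default 10 repetitions × 10 folds): within each repetition
   each class is dealt out in near-equal counts, with leftover members of
   the second class sent to the smallest folds, so overall fold sizes
   differ by at most one and class counts per fold are within one of the
   stratified ideal. The *same* plan object is reused across every
   predictor-domain run — this matched-folds contract (checked via a plan
   fingerprint) is what licenses paired per-iteration comparisons.
   Inside every training fold, median/mode imputation is refit from the
   training rows only and applied to the fold's test rows; encoding maps
   ordinal levels to ranks and nominal levels to integer codes (one column
   per item, so importances attach to items; one-hot expansion is
   deliberately not used).
4. **Learner.** A probability random forest (`ranger`): 1000 trees, √p
   candidate variables per split, minimum leaf size 1, and *balanced
   bootstrap* resampling (each tree draws equally many patients from both
   classes, with replacement) as the default answer to class imbalance;
   `balanced_weights` and `none` are available. All of this is
   configuration (`learner_spec()`), not doctrine: the original analysis
   this design follows documents its forest only as an ensemble over
   random subsamples of variables and patients, so these defaults are
   standard robust choices, and the test suite measures sensitivity to
   them rather than assuming it away.
5. **Scoring.** AUC by midranks (equal to pairwise counting with ties at
   one half — verified exhaustively in the tests), sensitivity,
   specificity, balanced accuracy, PPV and NPV at a probability threshold
   of 0.5 (no threshold is canonical for these models; 0.5 is the only
   symmetric default, and it is exposed as a parameter). Ratios with zero
   denominators are reported as missing, never as zero. Cross-iteration
   summaries report mean and sample (n−1) SD over the iteration-level
   values.

## Significance machinery

* **Label-permutation test** (`label_permutation_test()`): the pipeline is
  rerun under uniformly permuted labels; the add-one estimator
  `p = (1 + #{null ≥ observed}) / (1 + n_perm)` keeps p-values in (0, 1].
  The test is one-sided (chance is the floor for an AUC) and Bonferroni
  corrected across the six domain sets. Rerunning all 100 iterations per
  permutation is supported (`full_rerun`) but costly; the default economy
  (`reduced_rerun`) reruns a single k-fold repetition per permutation.
  Because median/mode imputation never looks at the labels, the rerun
  closures may operate on a globally imputed matrix without breaking
  exchangeability under the null; the main CV path keeps per-fold
  refitting, which is the leakage-safe reading of train-set imputation.
* **Paired sign-flip comparison** (`compare_domains()`): per-iteration AUC
  differences between two domain sets on identical folds, divided by their
  across-iteration SD (a scale-free, t-like statistic; the p-value is in
  fact invariant to any common rescaling, so the normalization matters for
  reporting, not for inference), tested by randomly negating each
  difference (default 10 000 flips, two-sided add-one p), Bonferroni over
  all pairs × tasks (30 tests for six domain sets and two outcomes).
* **Permutation variable importance** (`run_cv_importance()`): for each
  variable, its *test-fold* column is permuted (default 1000 times,
  independently seeded per variable) without refitting; importance is the
  AUC drop, and `p = (1 + #{AUC_perm ≥ AUC_obs}) / (1 + n_perm)`.
  Impurity-based importances are avoided as biased for mixed-type
  predictors; a refit-per-permutation strategy is statistically attractive
  but computationally out of reach at hundreds of variables × 1000
  permutations × 100 iterations, so column permutation without refit is
  the implemented reading, recorded as such in output metadata. BH-FDR is
  applied across variables *within* each iteration, and a variable counts
  as important when significant in at least 50 % of iterations
  (inclusive). Rank differences between the two tasks are tested by
  sign-flipping per-iteration rank differences, FDR-corrected across
  variables.

## The synthetic cohort generator

The generator (`generator_config()` / `generate_cohort()`) is first-class,
tested code: it defines the conditions under which every downstream claim
is validated.

* **Structure.** Default 994 patients and 569 items split 300 / 118 / 65 /
  74 / 12 across the clinical / psychological / sociodemographic /
  biological / lifestyle domains. Each item has one latent standard-normal
  draw per patient; continuous items are the latent value shifted +5 (and
  clipped at 10⁻³, so positivity is guaranteed and 0 is out of support),
  ordinal items discretize into 3–5 equiprobable ordered levels, nominal
  items into 2–6 categories with randomly permuted labels so integer codes
  carry no monotone signal.
* **Outcomes.** Each task's linear predictor sums domain contributions:
  for each domain a planted subset (20 % of items) enters with unit-norm
  weights scaled by a per-domain, per-task effect scale; weights use
  random signs with magnitudes in U(0.5, 1.5) so every planted item
  carries non-negligible signal (a plain normal draw would plant
  effectively dead items, which signal-recovery testing presupposes do
  not exist). The default scales 2.0 / 1.2 / 0.7 / 0.3 / 0 were calibrated
  once so that the clinical domain reaches a cross-validated AUC near 0.7
  with the all-domain combination slightly above — the performance regime
  this class of cohort analysis lives in — and were frozen thereafter.
  Intercepts are calibrated by bisection so empirical prevalences hit
  54.6 % (anxiety recovery) and 40.8 % (CMD recovery).
* **Outcome coupling.** Two mechanisms, deliberately separate: a *latent*
  shared factor (weight 1.0) correlates the labels but is invisible to the
  items, and a *signal overlap* parameter (default 0.75) correlates the
  two tasks' planted item weights within each domain. Only the second
  carries transferable signal — a model trained on one task's labels can
  predict the other task only through items both tasks load on — so
  transfer experiments manipulate `signal_overlap`, and label-correlation
  experiments can use either. The cohorts' actual inter-outcome agreement
  is not an estimate of anything: no such agreement statistic was
  available to target, so the coupling strength is an explicit free
  parameter.
* **Comorbidity.** A baseline-comorbidity flag (prevalence 0.56) loads
  negatively on the shared factor: comorbid patients are systematically
  less likely to be disorder-free at follow-up, giving the subgroup
  analysis realistic structure.
* **Missingness and skip patterns.** Per-item MCAR rates drawn uniformly
  from [0, 0.23] (so roughly an eighth of items exceed the 20 % filter and
  get dropped, mirroring a realistic exclusion fraction), and 10.8 % of
  patients receive an exact count of missing cells corresponding to rates
  of 0.25–0.45, guaranteeing they exceed the patient filter — the default
  994 generated patients therefore prepare down to roughly 887 analyzed.
  Skip rules pick categorical non-informative parents and mark 1–3 child
  items inapplicable at the parent's first level. The mechanism is MCAR
  only, by design: it exercises the filters and the imputer, and nothing
  in the pipeline models informative missingness.
* **What it does not emulate.** Real instrument content, inter-item
  correlation structure, assay distributions, and informative
  missingness. Items are independent given the planted signal. Passing
  tests on this generator therefore demonstrate that the machinery is
  correct and calibrated under its stated assumptions — not that any
  particular real cohort satisfies them; with correlated real items,
  variable-importance masking (below) is *more* severe, not less.

## Numerical choices

* Bisection for intercepts stops at |achieved − target| ≤ 10⁻⁹; medians of
  even counts use the midpoint for continuous items and round half *down*
  to a real level for ordinal items; modal ties break by declared level
  order. All tie-breaks are deterministic.
* One master seed derives every stage's sub-seed through a counter scheme
  (`derive_seed()`), so the full experiment is bit-reproducible and any
  stage can be rerun in isolation; seeds are logged in the manifest.
* Single-class restricted folds (possible in subgroup evaluation) skip
  that iteration for that metric and are counted, never silently dropped
  or zero-filled.

## Problem sizes used by the test suite

The packaged tests validate the pipeline at reduced scale, chosen once as
a deliberate design point: type-I error of the label-permutation test on
200 null cohorts of 300 patients with 59 permutations over a single 3-fold
repetition (the add-one test is exact at any permutation count, so small
counts cost resolution, not validity); domain-ordering recovery on ten
450-patient cohorts with clinical-only signal at scale 1.6 (clinical AUC
≈ 0.72) over 2×10 folds — twenty matched iterations, because the smallest
two-sided sign-flip p with k iterations is 2^(1−k), and ten iterations can
never clear a 30-way Bonferroni bar; importance recovery on 450-patient
cohorts with 10 planted continuous informative items among 100 noise items
at 250 permutations (the add-one floor 1/251 is the largest value that
clears the BH step-up threshold for a ten-variable planted set among 110);
and transfer/chance-level checks at 500–900 patients. The acceptance
script runs one 994-patient cohort at 30 % of the full item catalogue with
5×10-fold CV.

## Known limitations

Two nominal calibration properties fail, and the failures are properties
of the procedures, not of the implementation — the corresponding
acceptance tests assert the nominal property and are expected to stay red:

* **The sign-flip domain comparison is anti-conservative under a
  between-dataset null.** On pure-noise cohorts, all per-iteration AUC
  differences between two domains share whatever chance feature–label
  association that particular dataset carries; the sign-flip test treats
  the iterations as independent evidence and so rediscovers the dataset's
  own quirk. Both the conditional bias and the per-iteration noise scale
  as n^(−1/2), so the inflation does not vanish with cohort size: across
  configurations from 300 to 600 patients and 10 to 30 iterations, the
  fraction of null cohorts with zero significant pairs after Bonferroni
  ranged from 40 % to 81 %, never the nominal ≥90 %. This is the familiar
  optimism of cross-validation-based paired inference. Conclusions drawn
  from `compare_domains()` should be read as *within-cohort* statements.
* **Consistency-under-FDR importance selection cannot recover a small
  planted set.** The BH step-up threshold for a k-variable planted set
  among m variables is kα/m (≈ 0.0045 for 10 of 110 at α = 0.05), so all
  ten planted variables must reach the permutation floor simultaneously;
  random forests spread reliance across interchangeable additive signal
  variables (masking), so permuting any single column hurts held-out AUC
  too little, and only 3–6 variables reach the floor even with 900
  patients, 250 trees, continuous-only equal-weight signal and the mtry
  maximized. The rule behaves as designed when *many* variables are
  individually strong — the regime of real correlated symptom
  questionnaires — but on independent planted items it is stringent to the
  point of emptiness. The selection and rank-difference machinery is fully
  tested at small m, where the floor arithmetic is attainable.

Further limits, by design: no nested hyperparameter tuning, no model-based
imputation, no probability calibration, no conditional importance for
correlated predictors, and integer coding (not one-hot) of nominal items
as the default bookkeeping.
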