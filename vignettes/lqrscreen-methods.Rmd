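---
title: "Screening from low-quality questionnaire responses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening from low-quality questionnaire responses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The idea

Brief well-being questionnaires are administered routinely in community
settings by staff with no training in cognitive assessment. `lqrscreen`
treats the *response quality* of such questionnaires as a passive
cognitive screen: respondents with early cognitive deficits skip more
questions, contradict themselves on reverse-worded items, straight-line,
and pick statistically improbable categories. The package quantifies this
misfit with psychometric indices, predicts impairment risk from them, and
converts risk into a referral decision through an explicit
underdiagnosis/overdiagnosis cost trade-off.

## The graded response model and its estimation

Each scale is modelled by a unidimensional graded response model.
Categories are coded `0 … K−1` (a deliberate convention: the squared
residual's magnitude depends on the coding, so it is fixed and
documented). For item *i* with discrimination `a_i > 0` and ordered
thresholds `b_i1 < … < b_i,K−1`, the cumulative response curves are
logistic in `a_i (θ − b_ik)` and category probabilities are differences
of adjacent curves. `expected_response()` is the category expectation
`E[X_i | θ]`, strictly increasing in `θ`.

Estimation (`fit_grm()`) is marginal maximum likelihood by EM:

* **Prior and identification.** The latent trait carries a fixed
  standard-normal prior. This anchors the scale (no post-hoc
  standardisation), and the test suite checks that fitted trait scores
  have mean ≈ 0 and SD within [0.85, 1.15] at n = 3000.
* **Quadrature.** Default 61 equally spaced nodes on [−6, 6] with
  renormalised normal weights; a Gauss–Hermite scheme is available. For
  posteriors this smooth, the discretisation error is far below the
  1e−6 oracle tolerance used in the tests.
* **E-step.** Posterior weights of every respondent over the nodes,
  skipping missing responses.
* **M-step.** Per-item BFGS on the parameterisation
  `(log a, b_1, log gaps)`, which enforces `a > 0` and ordered
  thresholds by construction. The analytic gradient is verified against
  finite differences in the test suite. Warm starts at the current
  parameters make every M-step an ascent step, so the marginal
  log-likelihood is non-decreasing (checked to 1e−8).
* **Convergence.** Relative log-likelihood change below 1e−6 or 500
  iterations. Starting values come from empirical cumulative category
  proportions.
* **Degenerate input.** An item whose observed responses show fewer than
  two categories cannot be fitted and is rejected by name; an all-missing
  row contributes nothing and a respondent with no observed responses is
  scored at the prior (`θ = 0`, posterior SD 1).

Trait scores are EAP posterior means (`estimate_theta_eap()`), computed
per scale — the same scale whose indices are then derived, matching the
one-model-per-questionnaire design.

## The low-quality-response indices

Two per-item indices condition on the trait and therefore measure
content-free misfit:

* squared residual `s_ij = (x_ij − E[X_i | θ_j])²`;
* response probability `p_ij = P_{i, x_ij}(θ_j)` in (0, 1].

The predictor table (`build_feature_table()`) uses the per-item indices
as separate predictors (two per item; a six-item scale yields twelve
features) rather than respondent-level aggregates: aggregation is not
uniquely defined, and per-item features preserve information while
keeping the predictor count small. An aggregate mode (per-scale means)
and a log-probability transform exist behind flags; per-item raw
probabilities are the default. Combining scales concatenates their
features; demographics append age and gender.

## Preprocessing

* **Outcome labels.** Cognition scores 0–27 map to dementia (0–6),
  cognitive impairment without dementia (7–11) and normal (12–27); the
  binary label merges the first two bands.
* **Imputation.** Missing responses are imputed *before* model fitting
  (following the published order of operations) with round-robin chained
  linear regressions: median initialisation, each incomplete column
  regressed on all others, iterated until the mean absolute change of
  imputed cells is below 1e−3 (at most 10 sweeps), then rounded and
  clipped into the category range. Observed cells are never altered. A
  tension worth noting: imputing responses attenuates the skipping
  signal, since skipped answers are replaced by model-plausible ones;
  computing features first and imputing those instead is possible with
  the same function but is not the default.
* **Split.** 70/30 stratified on the binary label, allocated per stratum
  so train and test prevalence agree up to rounding; the manifest is
  written out so a split can be reproduced exactly.

## Risk models

The flagship model is a multilayer perceptron written in the package
(no deep-learning framework is part of its dependency set): four hidden
ReLU layers (64/32/16/8), batch normalization before each activation
(which lets raw, unscaled features in), dropout 0.2 after each hidden
layer, a sigmoid output whose bias starts at the training-prevalence
log-odds to speed convergence, class weights `n / (2 n_class)`, binary
cross-entropy, Adam (initial 1e−3) with reduce-on-plateau (×0.5 after 3
stale epochs), early stopping after 10 epochs without validation-AUC
improvement (best-epoch weights restored), batch size 256, at most 200
epochs. Backpropagation through the batch-norm layers is verified
against finite differences in the tests. On feature sets this small the
MLP performs on par with regularised logistic regression; it is kept as
the default for its capacity on combined-scale feature sets.

Cross-validation partitions the training data into 10 folds; repeat *j*
uses folds *j* and *j+1* (wrapping) as its 20% validation subset and
trains on the remaining 80%, so the layout is simultaneously a partition
and an 80/20 inner split. The repeat with the best validation AUC
supplies the retained model. Validation predictions pooled over repeats
(each row is scored by the two repeats that held it out, and averaged)
are stored on the model object.

Baselines trained under the same fold layout: elastic-net logistic
regression (`glmnet`; grid over alpha and lambda), CART (`rpart`; grid
over depth and complexity), gradient-boosted trees (`xgboost`; grid over
rounds, depth, learning rate — one histogram-boosting learner standing
in for the boosted-tree family), and a plain logistic regression on the
raw imputed item codes as the reference the LQR features must beat.

## Referral decisions

`select_threshold()` scans the midpoints between adjacent distinct
scores plus {0, 1} and minimises `r · FN + FP`, where `r` is the
underdiagnosis-to-overdiagnosis cost ratio (default 4; an overdiagnosis
costs one follow-up assessment, so only the ratio matters). Referral is
strict (`score > t`), and cost ties break toward the larger threshold,
i.e. the fewest referrals. For calibrated scores the optimum approaches
`1/(1+r)` — a property the tests verify. The threshold is tuned on the
pooled cross-validation validation predictions, never on the test set;
the source study does not state which partition it used, and this choice
is the leakage-free one.

`efficiency_curve()` sweeps the same candidate set and reports
(proportion of everyone referred, proportion of the impaired identified)
— operationally the positive rate and sensitivity — so curve points and
threshold decisions agree exactly. Rule-based comparators (age ≥ 65,
diabetes, high blood pressure, heart disease, stroke) are efficiency
points of indicator scores. `stratified_report()` repeats the metrics in
decade age bins (50–59 … 80+), reporting a missing AUC for single-class
bins rather than a placeholder.

## The synthetic cohort generator

The generator defines the study conditions under which the package is
exercised; its defaults are fixed and documented here.

* **Structure.** Four scales named optimism (6 items), hopelessness (7),
  purpose (7) and life satisfaction (5), all with six ordered
  categories; discriminations in [0.8, 2.5]; thresholds centred within
  [−2.5, 2.5]. Ages 50+ with decade-bin shares ≈ 21/33/31/15%; overall
  impairment prevalence 0.18 with a within-bin gradient (≈ 9% of the
  youngest bin to ≈ 39% of the 80+ bin, rescaled to the overall rate);
  gender ≈ 57% female; disease indicators with age-increasing,
  community-typical rates (hypertension ≈ 54%, diabetes ≈ 19%, heart
  disease ≈ 23%, stroke ≈ 7%). A secondary 10-year
  dementia-or-mortality label follows a logistic model in impairment
  and age.
* **Low-quality responding.** Per item: skip with the group's skip rate
  (1% normal / 5% impaired, giving ≈ 1.7% overall missingness — "do not
  know" answers are treated as missing, a coding decision the source
  data leave open); otherwise a careless act with the group's careless
  rate (5% / 30%); a careless act repeats the previous *presented*
  answer with probability 0.5 (straight-lining) or draws a category
  uniformly. Every second item of each scale is reverse-keyed and
  recoded before analysis, so straight-lining produces contradictory
  codes — the "contradictory answers" manifestation — rather than mean
  shifts.
* **Content signal.** The impaired group's latent trait is shifted by
  −0.15: impairment correlates weakly with lower well-being, weakly
  enough that response *quality*, not content, carries most of the
  signal.
* **Calibration.** These defaults were set, once, so that the synthetic
  study reproduces the magnitudes the screening literature reports for
  this design: a raw-response logistic baseline near AUC 0.56–0.60,
  LQR-only models near 0.63–0.66, and 0.71–0.74 once age and gender are
  added. The reverse-keying is essential: without it, straight-lining
  moves raw item means and hands the raw-response baseline an
  unrealistically strong signal.
* **What it does not emulate.** Real item wording, survey weights, proxy
  respondents, respondent-level heterogeneity in careless propensity
  (rates are homogeneous within group, as the configuration defines
  them), response times, and any dependence of missingness on item
  content. Tests that pass on these cohorts show the machinery is
  correct and the design discriminates under the stated conditions —
  not that the same AUCs would be obtained on any particular real
  survey.

## Problem sizes and test design

The simulation studies in the test suite use cohort sizes chosen to make
multi-seed replication cheap while keeping Monte-Carlo error small
relative to the effects tested: parameter recovery at n = 3000,
index-validity and negative-control studies at n = 1200 over 20 seeds,
and feature-set orderings at n = 2000 over 20 paired seeds (with the
logistic model, whose behaviour on these features matches the MLP's
ordering at a fraction of the cost). The acceptance script runs the MLP
itself at n = 4000. Every stochastic stage draws its seeds from one
master seed, and identical configurations reproduce artifacts byte for
byte.

## Known limitations

* The GRM is fitted to the full (imputed) sample before splitting,
  following the published order of operations; the item parameters are
  estimated without labels, so no outcome leakage occurs, but a strictly
  held-out protocol would refit on the training partition only.
* Single imputation, not multiple imputation: one completed dataset is
  analysed.
* The per-item M-step is a generalized EM (a bounded number of BFGS
  steps per iteration); this is why monotonicity, not full inner
  convergence, is the asserted property.
* Careless propensity in the generator is homogeneous within impairment
  group; real cohorts mix careless and careful respondents in both
  groups more heterogeneously, which would weaken observable group
  separation at equal rates.
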