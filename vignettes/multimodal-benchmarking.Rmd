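---
title: "Benchmarking multimodal predictors of immunotherapy outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multimodal predictors of immunotherapy outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reliable baseline biomarkers for immunotherapy outcome in metastatic
non-small cell lung cancer remain elusive. Candidate signals live in four
very different data modalities — routine clinical variables, whole-body
FDG-PET radiomics, pathomics from digitized biopsy slides, and bulk
transcriptomics — and real multimodal cohorts are small, partially
overlapping (most patients miss at least one modality), and access
restricted. `immunofuse` implements the full benchmarking machinery for
this setting: unimodal baselines, three integration strategies, a repeated
stratified cross-validation design with complete-profile-restricted
scoring, permutation-based inference, consensus feature importance, and
risk stratification — together with a synthetic cohort generator so that
every stage is exercised end-to-end without patient data.

## The synthetic cohort generator

`generate_cohort()` emulates the structure such a study assumes rather
than any particular dataset's values:

* Each modality $k$ has latent factors $z_k \sim N(0,1)$; its feature
  block is a random linear loading of those latents plus Gaussian noise.
  A configurable fraction of clinical features is binarized to mimic
  one-hot-encoded categorical variables.
* The log hazard is $\eta = \sum_k \beta_k z_{k1}$: each modality's
  *first* latent carries its prognostic signal, with per-modality effect
  sizes $\beta_k$. OS and PFS are exponential with hazards
  $h_{0}e^{\eta}$; PFS uses a larger baseline hazard so its median is
  shorter than the OS median, qualitatively matching advanced-NSCLC
  cohorts. Baseline hazards default to medians of 756 days (OS) and 296
  days (PFS) for a zero-risk patient; because risk is heterogeneous the
  marginal cohort medians are shorter.
* Censoring is the minimum of an administrative five-year window and, for
  a configurable fraction of patients (default 0.35), a uniform dropout
  time. These defaults give event rates around 60–70%, in the range of
  first-line immunotherapy cohorts.
* Binary endpoints are derived at fixed horizons — 365 days for 1-year
  death and 183 days for 6-month progression (the study describes the
  horizons only in words; we fix 1 year = 365 d and 6 months = 183 d).
  A patient censored before the horizon is *excluded* (`NA`), never
  imputed.
* Block-wise missingness uses exact pattern counts by default: 317
  patients, all with clinical data, 201/236/134 with
  radiomics/pathomics/rna, and exactly 80 with a complete multimodal
  profile. Only those margins are published; the intermediate Venn cells
  of `default_pattern_counts()` are a fixed plausible completion of them.
* A master seed spawns per-purpose sub-seeds (cohort, missingness,
  lesions, CV, permutation, bootstrap), so different experiments on the
  same cohort share cross-validation schemes by construction.

What the generator does *not* emulate: realistic covariance beyond the
block/latent design, non-proportional hazards, informative censoring, or
any image/slide/sequence-level structure. Tests passing on these cohorts
therefore validate the *machinery* (contracts, arithmetic, calibration,
leakage-freedom), not clinical performance claims.

The lesion-level simulator `generate_lesion_cohort()` feeds the radiomics
module: Poisson lesion counts per anatomical region, lognormal metabolic
volumes, SUVmax bounded below by the 2.5 SUV segmentation threshold,
centroids in a body-sized box, occasional diffuse-disease flags, and
per-patient healthy-organ reference uptake and body surface area.

## Whole-body radiomics

`assemble_radiomics()` reduces a per-lesion table to exactly 30 features:
liver and spleen reference SUVmean, log-TMTV, invaded-organ count,
standardized Dmax (largest centroid separation / body surface area), the
coefficient of quartile dispersion of centroid-to-global-centroid
distances, and, per stage group, TMTV plus the mean/sd/max of SUVmax.
Design choices where the published description leaves freedom:

* The stage partition is fixed to six groups \{T, N, M1a, M1b, M1c,
  other\} — 6 whole-body features + 6 × 4 group statistics equals the
  printed count of 30. The region-to-group mapping is configurable
  (`default_stage_groups()`).
* Quartile dispersion is the coefficient of quartile dispersion
  $(Q_3-Q_1)/(Q_3+Q_1)$ with linear-interpolation (type-7) quartiles; the
  global centroid is unweighted by lesion volume.
* SUVmax standard deviations use the population ($\div n$) convention, so
  a single lesion yields 0 rather than `NA`.
* Diffuse-flagged lesions (lymphangitic spread and similar) are excluded
  from every volume- and distance-derived feature but retained in SUVmax
  statistics, whose values do not depend on segmentation quality.
* Body surface area is an input column; no BSA formula is imposed.
* All metabolic-volume features are mapped through $\log(x+1)$.

## Base learners

Two families per task behind one fit/predict contract
(`learner_spec()`, `fit_unimodal()`, `predict_unimodal()`):

| family | task | key settings |
|---|---|---|
| boosted trees (xgboost) | binary | defaults, `max_depth` 6, positive-class weight = #neg/#pos, native `NA` routing |
| penalized logistic (glmnet) | binary | elastic net, mixing 0.5, inverse regularization strength $C = 0.1$ (mapped to $\lambda = 1/(Cn)$), balanced class weights, iteration cap 2500 |
| survival forest (ranger) | survival | default forest, maximum tree depth 6, risk = aggregate cumulative hazard |
| penalized Cox (glmnet) | survival | elastic-net path with minimum regularization ratio 0.01, predictions at the path's end |

All but the boosted trees see robust scaling — $(x - \mathrm{median})/
\mathrm{IQR}$, a degenerate IQR of 0 forced to scale 1 — followed by
median imputation of continuous features and most-frequent imputation of
binary indicators, always fitted on training rows only.

Classifier probabilities can be recalibrated with Platt's logistic map
(`platt_calibrate()`): raw out-of-fold predictions from a stratified inner
10-fold CV of the training set are fitted by a one-variable logistic
regression with balanced class weights. When a class has fewer members
than folds, the fold count is reduced so every inner training part keeps
both classes. The slope is not constrained: a negative fitted slope would
flip the ranking, which we document rather than hide (in practice slopes
are positive whenever the raw model beats chance).

## Fusion strategies

**Late fusion** trains one unimodal model per modality on the patients
with that modality available and averages the predictions over the
modalities available at test time; a patient with none of the
combination's modalities gets `NA`. Survival risk scores are standardized
per modality before averaging, using the mean/sd of out-of-fold
predictions from an event-stratified inner CV of the training set (an sd
of 0 is forced to 1). Fused boosted-tree classifiers can be
Platt-recalibrated on inner-CV fused predictions; since that map is
monotone it cannot change rank metrics, and the scaled benchmark runs in
this package leave it off.

**Early fusion** concatenates per-modality preprocessed blocks into a
single learner. Missing modalities are zero-filled for linear models,
left `NA` for boosted trees, and *double-coded* for survival forests:
every feature appears twice, with sentinels $+10^6/-10^6$ for unavailable
patients, letting trees route missingness to either side of any split
(any sentinel beyond all split candidates behaves identically; the
magnitude is a documented constant). The optional quota selection
(`select_features()`) ranks all features by $|m - 0.5|$ (training-set
univariate AUC or concordance), removes features correlating above
$\rho = 0.7$ (Pearson, pairwise-complete) with a better-ranked survivor,
and keeps $\lfloor n_{total}/n_{modas} \rfloor$ features per modality
with $n_{total} = 40$; unimodal combinations skip selection. Ties in the
ranking are broken by modality order, then feature name, for determinism.

**DyAM** (dynamic attention with masking) is a binary classifier with,
per modality, a score head $u_k = \tanh(w_k^\top x_k + b_k)$ and an
attention head $a_k = \mathrm{softplus}(v_k^\top x_k + c_k) > 0$;
unavailable modalities are masked and the output is
$\sigma\!\big(\sum_{k \in \mathrm{avail}} \bar a_k u_k\big)$ with
$\bar a_k = a_k / \sum a$. The cited architecture specifies the heads but
not the combiner; this normalized attention-weighted sum is our
interpretation. Training uses class-weighted cross-entropy, Adam, a
learning rate of 0.01, 125 full-batch epochs and L2 strength $10^{-3}$
added to the gradient (weight-decay convention); the pathomics block is
reduced to 40 principal components fitted on training rows. Gradients are
hand-derived and checked against finite differences in the test suite.
`dyam_grid_search()` optimizes (rate, L2) over
$\{0.1, 0.01, 0.001\} \times \{10^{-2}, 10^{-3}, 10^{-4}\}$ by inner
stratified CV — the grid values are our choice, as only the strategy is
published. Per-modality weight initialization is seeded from the modality
name, making models invariant to the order the combination is written in.

`modality_shapley()` decomposes a fused prediction over modalities as
exact Shapley values of the coalition game $v(S) = \mathrm{mean}$ of the
predictions in $S$, with $v(\emptyset) = 0.5$, the random-classifier
baseline; efficiency $\sum_k \phi_k = v(\mathrm{full}) - 0.5$ holds
exactly.

## Evaluation design

`make_cv_schemes()` builds repeated (default 100) stratified 10-fold
schemes — stratified on class for classification and on the event
indicator for survival (the censorship rate) — that are reused across all
models for a given cohort and seed, so model comparisons are paired.
`run_benchmark()` drops patients with every combination modality missing
(and excluded labels) from each training fold, fits everything on
training rows only, and predicts the full test fold; within a fold, late
fusion shares the per-modality unimodal fits across combinations, which
is exact because a unimodal model's training subset does not depend on
the combination. `evaluate_restricted()` scores pooled out-of-fold
predictions per scheme — optionally on a subset such as the
complete-profile patients — and summarizes as mean ± sd over schemes.

Metrics are the tie-corrected rank AUC and Uno's IPCW concordance index,
truncated by default at the 95th percentile of observed follow-up (the
truncation point is not published; this default avoids unstable censoring
weights in the tail). Both are implemented directly and verified in the
tests against exhaustive pair counting and against
`survival::concordance(timewt = "n/G2")`.

Inference machinery: whole-pipeline permutation tests (shuffled
outcomes, one-sided $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$ — the +1
small-sample convention is ours), univariate biomarker tests with
percentile bootstrap CIs (default 10,000 resamples) and permutation
p-values on the distance $|m - 0.5|$ from chance (so protective and risk
directions both count), and a paired permutation comparison that swaps
two models' predictions per patient with probability one half within each
scheme, BH-adjusts the per-scheme p-values, and reports the fraction
significant. The same exchange applies to AUC and C-index, the latter
being the censored-data generalization of the former.

## Feature importance consensus

`shap_attributions()` computes model-agnostic Shapley attributions with a
background-marginalized value function: exact subset enumeration up to 10
features, antithetic permutation sampling beyond (each sampled order is
also walked in reverse; walks telescope, so local accuracy — attributions
summing to prediction minus baseline — holds in both regimes).
Attributions are computed only for test rows of each scheme and averaged
across schemes.

The consensus ranking per modality combines up to four models (two
related tasks × two families): features whose attribution/value Spearman
correlation sign disagrees across admissible models (score > 0.5) are
filtered out — a zero or undefined correlation counts as inconsistent,
the stricter reading; per model, robust features are ranked by mean
absolute attribution (1 = least important, ties broken by name); and the
consensus rank is the performance-weighted mean
$r^{cons}_f = \sum_i s_i r^f_i / \sum_i s_i$ with
$s_i = \max(0, score_i - 0.5)$, so chance-level models are provably
inert. Ranks are normalized by the robust-feature count and signed by the
attribution/value correlation direction; univariate permutation tests
with BH correction flag significant features.

## Risk stratification

For each fold, `learn_threshold()` scans the training-prediction
percentiles 30–70 (step 1, a grid of our choosing within the published
range) plus the 0.5 probability cutoff for classifiers, and keeps the
candidate maximizing the training log-rank statistic — equivalent to
minimizing the p-value while immune to underflow. PFS-trained models
optimize the threshold against PFS, mimicking settings where OS is
unavailable at training time. Degenerate candidate sets fall back to the
median. Test-fold memberships are aggregated over schemes by majority;
an exact 50% tie is conservatively assigned high risk. Kaplan-Meier
curves use Greenwood-based intervals; quartile stratification of averaged
scores splits by rank so ties cannot unbalance the groups. Multivariate
Cox models standardize all inputs for comparable hazard ratios, impute
missing covariates (median / most frequent) and missing model scores
(0.5 for classification, 0 for survival scores), and likelihood-ratio
tests compare nested models via $2\Delta\ell$ against $\chi^2$.

## Numerical and scale choices

Benchmark problem sizes in the tests and the acceptance script are scaled
down: cohorts of 80–300 patients, 1–20 repeated schemes, survival forests
of 50–200 trees, 2–3 inner standardization folds, and reduced permutation
counts (19–1000) — chosen so the whole suite re-runs in minutes on one
CPU while leaving every contract exercised at full fidelity. The
full-scale defaults (100 repeats, 10 inner folds, 500 trees, 10,000
bootstrap resamples) remain the package defaults.

Known limitations: DyAM is full-batch and single-layer by design; the
survival late fusion assumes inner-CV standardization constants transfer
to the test fold; exact Shapley enumeration is exponential and reserved
for small blocks; and synthetic-cohort results say nothing about absolute
performance on real multimodal NSCLC data.

## A minimal run

```{r example}
library(immunofuse)
library(survival)

co <- generate_cohort(cohort_config(seed = 1))
surv <- Surv(co$outcomes$os_time, co$outcomes$os_event)
schemes <- make_cv_schemes(co$outcomes$os_event, n_repeats = 5,
                           n_folds = 10, seed = 1)
store <- run_benchmark(co$data$blocks, co$data$availability, surv,
                       learner_spec("penalized_cox"),
                       combos = list("clinical", c("clinical", "rna")),
                       schemes = schemes, strategy = "late")
complete <- match(complete_profile_ids(co$data), co$data$patient_ids)
evaluate_restricted(store, "clinical+rna", surv, subset = complete)
```
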