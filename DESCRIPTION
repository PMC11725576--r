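Package: immunofuse
Title: Multimodal Fusion Benchmarking for Immunotherapy Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking unimodal and multimodal machine-learning
    predictors of immunotherapy outcome in metastatic non-small cell lung
    cancer from clinical, PET-radiomic, pathomic and transcriptomic feature
    blocks. Implements late fusion, early fusion with quota-based feature
    selection, and an attention-with-masking classifier that tolerates
    missing modalities; a repeated stratified cross-validation engine with
    complete-profile-restricted scoring by ROC AUC and Uno's concordance
    index; permutation and bootstrap inference with Benjamini-Hochberg
    correction; Shapley-based modality and feature attribution with a
    performance-weighted consensus feature ranking; and log-rank
    optimal-cutoff risk stratification with Kaplan-Meier, Cox and
    likelihood-ratio analyses. A synthetic multimodal cohort generator with
    block-wise modality missingness and latent-risk-driven censored survival
    outcomes, plus a per-lesion PET simulator feeding 30 whole-body radiomic
    aggregation features (TMTV, standardized Dmax, organ counts, stage-group
    SUV statistics), makes the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
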