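# Repeated stratified cross-validation engine with out-of-fold prediction
# stores and complete-profile-restricted scoring.
#
# One set of fold assignments (schemes) is generated per cohort + seed and
# reused across every model and modality combination, so paired comparisons
# between models contrast predictions obtained under identical data splits.

#' Generate repeated stratified cross-validation schemes
#'
#' Folds are stratified on class membership (classification) or on the event
#' indicator (survival, i.e. the censorship rate); per fold, stratum counts
#' differ by at most one patient. Patients with an excluded (`NA`) label form
#' their own stratum so they are still spread evenly over test folds.
#'
#' @param strata Vector defining the stratification variable: 0/1 labels
#'   (possibly `NA`) for classification, event indicators for survival.
#' @param n_repeats Number of repeated schemes (default 100).
#' @param n_folds Folds per scheme (default 10).
#' @param seed Master seed; repeat r uses a sub-seed derived from it.
#' @return List of length `n_repeats`; each element an integer fold
#'   assignment in `1..n_folds` per patient.
#' @export
make_cv_schemes <- function(strata, n_repeats = 100L, n_folds = 10L,
                            seed = 1L) {
  stopifnot(n_repeats >= 1, n_folds >= 2)
  s <- as.character(strata)
  s[is.na(s)] <- ".na"
  lapply(seq_len(n_repeats), function(r) {
    stratified_folds(s, n_folds, seed = sub_seed(seed, "cv") + r)
  })
}

#' Run a cross-validated multimodal benchmark
#'
#' For every scheme and fold: patients with every modality of a combination
#' missing (or an excluded label, for classification) are dropped from the
#' training set; preprocessing, feature selection and models are fitted on
#' training rows only; the full test fold is predicted. Late fusion shares
#' the per-modality unimodal fits across combinations within a fold, which
#' is exact because each unimodal model is trained on the patients with that
#' modality available regardless of the combination.
#'
#' @param blocks Named list of feature matrices (full cohort).
#' @param availability Logical matrix, patients x modalities.
#' @param outcome 0/1 labels (`NA` = excluded) or [survival::Surv].
#' @param spec A [learner_spec()].
#' @param combos List of modality character vectors (e.g.
#'   `list("clinical", c("clinical", "rna"))`).
#' @param schemes Result of [make_cv_schemes()].
#' @param strategy `"late"`, `"early"` or `"dyam"`.
#' @param selection Optional [selection_config()] (early fusion / DyAM).
#' @param dyam_cfg A [dyam_config()] for `strategy = "dyam"`.
#' @param calibrate Platt-recalibrate fused tree classifiers (late fusion).
#' @param inner_folds Folds of the inner CV that estimates the per-modality
#'   survival standardization constants (default 10; reduce for scaled-down
#'   benchmark runs).
#' @return A `prediction_store`: list with `task`, `combos`, and `preds`, a
#'   named list mapping `"mod1+mod2"` to a patients x repeats matrix of
#'   out-of-fold predictions (`NA` where undefined).
#' @export
run_benchmark <- function(blocks, availability, outcome, spec, combos,
                          schemes, strategy = c("late", "early", "dyam"),
                          selection = NULL, dyam_cfg = dyam_config(),
                          calibrate = FALSE, inner_folds = 10L) {
  strategy <- match.arg(strategy)
  n <- nrow(availability)
  n_rep <- length(schemes)
  combo_ids <- vapply(combos, paste, "", collapse = "+")
  preds <- lapply(combo_ids, function(id)
    matrix(NA_real_, n, n_rep))
  names(preds) <- combo_ids
  task <- if (strategy == "dyam") "binary" else spec$task
  labeled <- if (task == "binary") !is.na(outcome) else rep(TRUE, n)
  all_mods <- unique(unlist(combos))

  for (r in seq_len(n_rep)) {
    fold <- schemes[[r]]
    for (f in sort(unique(fold))) {
      test <- fold == f
      train <- !test & labeled

      if (strategy == "late") {
        # shared per-modality unimodal fits
        unim <- list(); stand <- list()
        for (k in all_mods) {
          rows <- train & availability[, k]
          if (!any(rows)) next
          oc <- outcome[rows]
          fit <- tryCatch(
            fit_unimodal(blocks[[k]][rows, , drop = FALSE], oc, spec),
            error = function(e) NULL)
          if (is.null(fit)) next
          unim[[k]] <- fit
          if (spec$task == "survival")
            stand[[k]] <- inner_cv_standardization(
              blocks[[k]][rows, , drop = FALSE], oc, spec, inner_folds)
        }
        test_rows <- which(test)
        pm <- matrix(NA_real_, length(test_rows), length(all_mods),
                     dimnames = list(NULL, all_mods))
        for (k in names(unim)) {
          av <- availability[test_rows, k]
          if (!any(av)) next
          p <- predict_unimodal(unim[[k]],
                                blocks[[k]][test_rows[av], , drop = FALSE])
          if (spec$task == "survival")
            p <- (p - stand[[k]]$mean) / stand[[k]]$sd
          pm[av, k] <- p
        }
        for (ci in seq_along(combos)) {
          cb <- intersect(combos[[ci]], names(unim))
          if (!length(cb)) next
          preds[[combo_ids[ci]]][test_rows, r] <-
            fuse_predictions(pm[, cb, drop = FALSE])
        }
      } else {
        for (ci in seq_along(combos)) {
          cb <- combos[[ci]]
          tr <- train & rowSums(availability[, cb, drop = FALSE]) > 0
          if (!any(tr)) next
          sub_blocks <- lapply(blocks, function(b) b[tr, , drop = FALSE])
          sub_av <- availability[tr, , drop = FALSE]
          te_blocks <- lapply(blocks, function(b) b[test, , drop = FALSE])
          te_av <- availability[test, , drop = FALSE]
          p <- tryCatch({
            if (strategy == "early") {
              m <- train_early_fusion(sub_blocks, sub_av, outcome[tr], cb,
                                      spec, selection)
              predict_early_fusion(m, te_blocks, te_av)
            } else {
              cfgr <- dyam_cfg
              cfgr$seed <- dyam_cfg$seed + r
              m <- train_dyam(sub_blocks, sub_av, outcome[tr], cb, cfgr,
                              selection)
              predict_dyam(m, te_blocks, te_av)
            }
          }, error = function(e) rep(NA_real_, sum(test)))
          # predictions undefined when the patient has no combo modality
          none <- rowSums(te_av[, cb, drop = FALSE]) == 0
          p[none] <- NA_real_
          preds[[combo_ids[ci]]][test, r] <- p
        }
      }
    }
  }
  structure(list(task = task, combos = combos, combo_ids = combo_ids,
                 preds = preds, n_repeats = n_rep),
            class = "prediction_store")
}

#' Score a prediction store on a patient subset
#'
#' Computes the metric per repeated scheme on the pooled out-of-fold
#' predictions of the subset (e.g. the patients with a complete multimodal
#' profile), then summarizes as mean and standard deviation over repeats.
#'
#' @param store A [run_benchmark()] result.
#' @param combo_id Combination id (`"clinical+rna"`).
#' @param outcome 0/1 labels or [survival::Surv] for the full cohort.
#' @param subset Integer or logical index of patients to score (default:
#'   everyone).
#' @param tau Truncation time for Uno's C (survival task).
#' @return List with `mean`, `sd` and `per_repeat` metric values.
#' @export
evaluate_restricted <- function(store, combo_id, outcome,
                                subset = NULL, tau = NULL) {
  stopifnot(inherits(store, "prediction_store"),
            combo_id %in% names(store$preds))
  pm <- store$preds[[combo_id]]
  if (is.null(subset)) subset <- seq_len(nrow(pm))
  pm <- pm[subset, , drop = FALSE]
  if (store$task == "binary") {
    y <- outcome[subset]
    vals <- apply(pm, 2, roc_auc, labels = y)
  } else {
    tm <- outcome[subset, "time"]; ev <- outcome[subset, "status"]
    vals <- apply(pm, 2, uno_cindex, time = tm, event = ev, tau = tau)
  }
  list(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
       per_repeat = vals)
}
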