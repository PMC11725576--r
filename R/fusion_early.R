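# Early fusion: concatenate per-modality preprocessed feature blocks into a
# single learner, with an optional quota-based univariate feature selection
# that keeps the total feature count comparable across combinations.
# Missing modalities are handled per learner family: zero-filled blocks for
# linear models, native NA routing for boosted trees, and double-coding
# (high/low sentinel duplicates) for survival forests.

#' Feature-selection configuration for early fusion
#'
#' @param n_total Total feature budget across modalities (default 40).
#' @param rho Pearson-correlation redundancy threshold (default 0.7).
#' @return A `selection_config`.
#' @export
selection_config <- function(n_total = 40L, rho = 0.7) {
  stopifnot(rho > 0, rho < 1, n_total >= 1)
  structure(list(n_total = as.integer(n_total), rho = rho),
            class = "selection_config")
}

#' Quota-based univariate feature selection
#'
#' Scores every feature of the combination's modalities with
#' `|m - 0.5|`, where `m` is the training-set univariate AUC (binary task)
#' or concordance (survival task); ranks all features jointly in decreasing
#' score (ties broken by modality order, then feature name); walks the
#' ranking top-down removing any feature whose absolute Pearson correlation
#' with an already-kept feature exceeds `rho` (pairwise-complete
#' observations); and finally keeps, per modality, its top
#' `floor(n_total / n_modalities)` surviving features. Unimodal
#' combinations skip selection and keep every feature.
#'
#' @param blocks Named list of training feature matrices.
#' @param availability Logical matrix, training rows x modalities.
#' @param outcome 0/1 labels or [survival::Surv], aligned with rows.
#' @param combo Modalities of the combination.
#' @param cfg A [selection_config()].
#' @param task `"binary"` or `"survival"`.
#' @return Named list, per modality, of selected feature names.
#' @export
select_features <- function(blocks, availability, outcome, combo,
                            cfg = selection_config(),
                            task = c("binary", "survival")) {
  task <- match.arg(task)
  if (length(combo) == 1)
    return(stats::setNames(list(colnames(blocks[[combo]])), combo))

  feats <- list()
  for (k in combo) {
    rows <- availability[, k]
    b <- blocks[[k]][rows, , drop = FALSE]
    oc <- outcome[rows]
    score <- vapply(seq_len(ncol(b)), function(j) {
      m <- univariate_metric(b[, j], oc, task)
      if (is.na(m)) 0 else abs(m - 0.5)
    }, numeric(1))
    feats[[k]] <- data.frame(modality = k, feature = colnames(b),
                             score = score, stringsAsFactors = FALSE)
  }
  all_feats <- do.call(rbind, feats)
  all_feats$mod_order <- match(all_feats$modality, combo)
  ord <- order(-all_feats$score, all_feats$mod_order, all_feats$feature)
  all_feats <- all_feats[ord, ]

  # correlation filter on training rows, pairwise-complete
  col_of <- function(mod, f) blocks[[mod]][availability[, mod], f]
  kept <- list()
  kept_cols <- list()
  for (i in seq_len(nrow(all_feats))) {
    mod <- all_feats$modality[i]; f <- all_feats$feature[i]
    v <- blocks[[mod]][, f]
    redundant <- FALSE
    for (kc in kept_cols) {
      r <- suppressWarnings(
        stats::cor(v, kc, use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > cfg$rho) { redundant <- TRUE; break }
    }
    if (!redundant) {
      kept[[length(kept) + 1L]] <- all_feats[i, c("modality", "feature")]
      kept_cols[[length(kept_cols) + 1L]] <- v
    }
  }
  kept <- do.call(rbind, kept)

  quota <- cfg$n_total %/% length(combo)
  out <- list()
  for (k in combo) {
    surv <- kept$feature[kept$modality == k]
    out[[k]] <- utils::head(surv, quota)
  }
  out
}

#' Double-code a feature block for tree-based missing-modality handling
#'
#' Emits every feature twice; patients with the modality unavailable receive
#' a very high value (+S) in the first copy and a very low value (-S) in the
#' second, letting survival trees route them to either side of any split.
#' Available patients carry the original value in both copies.
#'
#' @param block Feature matrix (already preprocessed for available rows).
#' @param available Logical vector over rows.
#' @param sentinel Sentinel magnitude (default 1e6, far outside the
#'   robust-scaled data range).
#' @return Matrix with twice the columns (`<f>_hi`, `<f>_lo`).
#' @export
double_code <- function(block, available, sentinel = 1e6) {
  block <- as.matrix(block)
  hi <- lo <- block
  hi[!available, ] <- sentinel
  lo[!available, ] <- -sentinel
  colnames(hi) <- paste0(colnames(block), "_hi")
  colnames(lo) <- paste0(colnames(block), "_lo")
  cbind(hi, lo)
}

#' Train an early-fusion model
#'
#' Preprocesses each modality on its available training patients, optionally
#' applies [select_features()], concatenates the blocks, and fits a single
#' base learner. Missing-modality cells are zero-filled for linear families,
#' left `NA` for boosted trees, and double-coded for survival forests.
#'
#' @inheritParams train_late_fusion
#' @param selection A [selection_config()] or `NULL` to keep all features.
#' @return An `early_fusion_model`.
#' @export
train_early_fusion <- function(blocks, availability, outcome, combo, spec,
                               selection = NULL) {
  stopifnot(length(combo) >= 1, all(combo %in% colnames(availability)))
  keep <- rowSums(availability[, combo, drop = FALSE]) > 0
  if (spec$task == "binary") keep <- keep & !is.na(outcome)
  blocks <- lapply(blocks, function(b) b[keep, , drop = FALSE])
  availability <- availability[keep, , drop = FALSE]
  outcome <- outcome[keep]

  selected <- if (is.null(selection))
    stats::setNames(lapply(combo, function(k) colnames(blocks[[k]])), combo)
  else select_features(blocks, availability, outcome, combo, selection,
                       task = spec$task)

  prep <- list()
  for (k in combo) {
    if (!length(selected[[k]])) next
    if (spec$family == "boosted_trees_classifier") { prep[k] <- list(NULL); next }
    rows <- availability[, k]
    prep[[k]] <- fit_preprocessor(
      blocks[[k]][rows, selected[[k]], drop = FALSE])
  }
  model <- structure(list(combo = combo, spec = spec, selected = selected,
                          preproc = prep),
                     class = "early_fusion_model")
  xx <- assemble_early_matrix(model, blocks, availability)
  model$fit <- fit_unimodal(xx, outcome, spec, preprocess = FALSE)
  model
}

# Concatenated design matrix with per-family missing-modality encoding.
assemble_early_matrix <- function(model, blocks, availability) {
  parts <- list()
  for (k in model$combo) {
    sel <- model$selected[[k]]
    if (!length(sel)) next
    b <- blocks[[k]][, sel, drop = FALSE]
    av <- availability[, k]
    if (model$spec$family == "boosted_trees_classifier") {
      b[!av, ] <- NA                      # native NA routing
    } else {
      out <- apply_preprocessor(model$preproc[[k]], b[av, , drop = FALSE])
      scaled <- matrix(0, nrow(b), length(sel))
      scaled[av, ] <- out
      colnames(scaled) <- sel
      b <- scaled                         # zero-fill missing modalities
      if (model$spec$family == "survival_forest")
        b <- double_code(b, av)
    }
    colnames(b) <- paste0(k, ".", colnames(b))
    parts[[k]] <- b
  }
  do.call(cbind, parts)
}

#' Predict from an early-fusion model
#'
#' @param model A [train_early_fusion()] result.
#' @param blocks Named list of feature matrices for the rows to predict.
#' @param availability Logical matrix, rows x modalities.
#' @return Probabilities (binary) or risk scores (survival).
#' @export
predict_early_fusion <- function(model, blocks, availability) {
  stopifnot(inherits(model, "early_fusion_model"))
  xx <- assemble_early_matrix(model, blocks, availability)
  predict_unimodal(model$fit, xx)
}
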