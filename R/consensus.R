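# Consensus feature importance across models.
#
# Combines the Shapley attributions of up to four models per modality (two
# related tasks x two learner families): a robustness filter keeps only
# features whose attribution/value correlation sign agrees across admissible
# models (score above the 0.5 chance level); per model, robust features are
# ranked by mean absolute attribution (1 = least important); and ranks are
# aggregated with performance weights s_i = max(0, score_i - 0.5), so models
# at or below chance are provably inert. Consensus ranks are normalized by
# the robust-feature count and signed by the direction of the
# attribution/value relation.

#' Robustness filter on attribution sign consistency
#'
#' Computes, per feature and per model, the Spearman correlation between the
#' feature's attributions and its values, and keeps the features whose
#' correlation sign is identical across all admissible models. Models with a
#' score at or below 0.5 are excluded from the check; a zero or undefined
#' correlation counts as inconsistent.
#'
#' @param attributions List (one per model) of patients x features
#'   mean-attribution matrices with identical column names.
#' @param values Patients x features matrix of the feature values.
#' @param scores Numeric vector of model scores (AUC or C-index).
#' @return List with `robust` (kept feature names), `signs` (named sign
#'   vector of the kept features) and `sign_matrix` (models x features).
#' @export
robustness_filter <- function(attributions, values, scores) {
  stopifnot(length(attributions) == length(scores))
  admissible <- which(scores > 0.5)
  if (length(admissible) < 1)
    stop("no admissible model (all scores <= 0.5)")
  feats <- colnames(values)
  sign_mat <- matrix(NA_real_, length(attributions), length(feats),
                     dimnames = list(NULL, feats))
  for (i in seq_along(attributions)) {
    a <- attributions[[i]]
    stopifnot(identical(colnames(a), feats))
    for (f in feats) {
      ok <- !is.na(a[, f]) & !is.na(values[, f])
      if (sum(ok) > 2 && stats::sd(values[ok, f]) > 0 &&
          stats::sd(a[ok, f]) > 0) {
        r <- stats::cor(a[ok, f], values[ok, f], method = "spearman")
        sign_mat[i, f] <- sign(r)
      }
    }
  }
  keep <- vapply(feats, function(f) {
    s <- sign_mat[admissible, f]
    all(!is.na(s)) && all(s != 0) && length(unique(s)) == 1
  }, TRUE)
  robust <- feats[keep]
  signs <- vapply(robust, function(f) sign_mat[admissible[1], f], 0)
  list(robust = robust, signs = signs, sign_matrix = sign_mat)
}

#' Per-model importance ranks of robust features
#'
#' Ranks features by mean absolute attribution across patients, with
#' 1 = least important and `n_F` = most important; ties broken by feature
#' name for determinism.
#'
#' @param attributions Patients x features matrix for one model.
#' @param robust Feature names retained by [robustness_filter()].
#' @return Named integer rank vector over the robust features.
#' @export
importance_ranks <- function(attributions, robust) {
  imp <- colMeans(abs(attributions[, robust, drop = FALSE]), na.rm = TRUE)
  ord <- order(imp, names(imp))           # ascending: rank 1 = least important
  r <- integer(length(robust))
  r[ord] <- seq_along(ord)
  stats::setNames(r, robust)
}

#' Performance-weighted consensus rank
#'
#' `r_cons(f) = sum_i s_i r_i(f) / sum_i s_i` with weights
#' `s_i = max(0, score_i - 0.5)`; a model at or below the chance level has
#' zero weight and cannot influence the ranking.
#'
#' @param ranks Matrix models x features of per-model ranks (1 = least
#'   important), or a list of equally named rank vectors.
#' @param scores Numeric model scores (AUC / C-index), one per row.
#' @return List with `consensus` (named numeric rank per feature),
#'   `normalized` (consensus / n_F, in (0, 1]) and `weights`.
#' @export
consensus_rank <- function(ranks, scores) {
  if (is.list(ranks)) ranks <- do.call(rbind, ranks)
  stopifnot(nrow(ranks) == length(scores))
  w <- pmax(0, scores - 0.5)
  if (sum(w) <= 0) stop("all model weights are zero (scores <= 0.5)")
  cons <- colSums(ranks * w) / sum(w)
  nf <- ncol(ranks)
  list(consensus = cons, normalized = cons / nf, weights = w)
}

#' Univariate significance of robust features
#'
#' One-sided permutation p-value per feature and task on the distance of the
#' univariate AUC / concordance from the 0.5 chance level, followed by
#' Benjamini-Hochberg adjustment across features within each task.
#'
#' @param values Patients x features matrix (robust features).
#' @param outcomes Named list of outcome objects (0/1 labels or
#'   [survival::Surv]), one per task.
#' @param n_perm Permutations (default 1000).
#' @param alpha FDR level (default 0.05).
#' @param seed Integer seed.
#' @return Data frame: feature, then per task the raw and adjusted p-value
#'   and a significance flag.
#' @export
univariate_feature_significance <- function(values, outcomes,
                                            n_perm = 1000L, alpha = 0.05,
                                            seed = 1L) {
  feats <- colnames(values)
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (task in names(outcomes)) {
    p <- vapply(feats, function(f) {
      univariate_biomarker_test(values[, f], outcomes[[task]],
                                n_perm = n_perm, n_boot = 2L,
                                seed = seed)$p
    }, numeric(1))
    adj <- bh_adjust(p, alpha)
    out[[paste0("p_", task)]] <- p
    out[[paste0("p_adj_", task)]] <- adj$adjusted
    out[[paste0("significant_", task)]] <- adj$reject
  }
  out
}

#' Full consensus feature ranking for one modality
#'
#' Chains [robustness_filter()], [importance_ranks()], [consensus_rank()]
#' and [univariate_feature_significance()] into the final ranking table.
#'
#' @param attributions List of per-model mean-attribution matrices.
#' @param values Patients x features matrix of feature values.
#' @param scores Per-model scores (AUC / C-index).
#' @param outcomes Named list of task outcomes for the univariate tests, or
#'   `NULL` to skip them.
#' @param n_perm,alpha,seed Passed to the univariate tests.
#' @return Data frame with one row per robust feature: `feature`,
#'   `consensus_rank`, `normalized_rank`, `sign`, plus per-task adjusted
#'   p-values; ordered from most to least important.
#' @export
consensus_feature_ranking <- function(attributions, values, scores,
                                      outcomes = NULL, n_perm = 1000L,
                                      alpha = 0.05, seed = 1L) {
  filt <- robustness_filter(attributions, values, scores)
  if (!length(filt$robust))
    return(data.frame(feature = character(0), consensus_rank = numeric(0),
                      normalized_rank = numeric(0), sign = numeric(0)))
  ranks <- do.call(rbind, lapply(attributions, importance_ranks,
                                 robust = filt$robust))
  cons <- consensus_rank(ranks, scores)
  out <- data.frame(feature = filt$robust,
                    consensus_rank = cons$consensus,
                    normalized_rank = cons$normalized,
                    sign = filt$signs,
                    stringsAsFactors = FALSE)
  if (!is.null(outcomes)) {
    sig <- univariate_feature_significance(
      values[, filt$robust, drop = FALSE], outcomes, n_perm, alpha, seed)
    out <- merge(out, sig, by = "feature", sort = FALSE)
  }
  out[order(-out$consensus_rank, out$feature), ]
}
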