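# Statistical inference for the benchmark: whole-pipeline permutation tests,
# univariate biomarker tests with bootstrap confidence intervals, paired
# permutation comparison of two models across repeated CV schemes, and
# Benjamini-Hochberg multiple-testing control.

#' Whole-pipeline permutation test
#'
#' Re-runs a user-supplied pipeline closure on outcome vectors with randomly
#' shuffled patient assignment and compares the observed metric with the
#' null distribution. Uses the one-sided small-sample-corrected p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param run_fn Function `outcome -> metric`; must re-run the full pipeline
#'   (CV, preprocessing, fitting, scoring) for the outcome it is given.
#' @param outcome The observed outcome object; permutations shuffle patient
#'   order. Works for vectors and for [survival::Surv] objects.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutations.
#' @return List with `observed`, `null` (length `n_perm`) and `p`.
#' @export
pipeline_permutation_test <- function(run_fn, outcome, n_perm = 100L,
                                      seed = 1L) {
  observed <- run_fn(outcome)
  n <- if (survival::is.Surv(outcome)) nrow(outcome) else length(outcome)
  set.seed(sub_seed(seed, "permutation"))
  null <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    run_fn(if (survival::is.Surv(outcome)) outcome[idx, ] else outcome[idx])
  }, numeric(1))
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}

# Effect-size statistic shared by the univariate tests: distance of the
# C statistic from the 0.5 chance level.
chance_distance <- function(m) abs(m - 0.5)

#' Univariate biomarker test
#'
#' Scores a single feature by AUC (binary outcome) or concordance (survival
#' outcome), with a percentile bootstrap confidence interval and a one-sided
#' permutation p-value on the distance of the statistic from the 0.5 chance
#' level (so both risk and protective directions count as signal).
#'
#' @param feature Numeric feature vector.
#' @param outcome 0/1 labels or [survival::Surv].
#' @param n_perm Label permutations (default 1000).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf Confidence level of the bootstrap interval.
#' @param seed Integer seed.
#' @return List with `metric`, `ci` (length 2), `p`.
#' @export
univariate_biomarker_test <- function(feature, outcome, n_perm = 1000L,
                                      n_boot = 10000L, conf = 0.95,
                                      seed = 1L) {
  if (length(unique(feature[!is.na(feature)])) < 2)
    return(list(metric = NA_real_, ci = c(NA_real_, NA_real_),
                p = NA_real_))
  surv <- survival::is.Surv(outcome)
  score <- function(f, oc) {
    if (surv) harrell_cindex(f, oc[, "time"], oc[, "status"])
    else roc_auc(f, oc)
  }
  metric <- score(feature, outcome)
  n <- length(feature)

  set.seed(sub_seed(seed, "bootstrap"))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    score(feature[idx], if (surv) outcome[idx, ] else outcome[idx])
  }, numeric(1))
  alpha <- 1 - conf
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)

  set.seed(sub_seed(seed, "permutation"))
  null <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    score(feature, if (surv) outcome[idx, ] else outcome[idx])
  }, numeric(1))
  p <- (1 + sum(chance_distance(null) >= chance_distance(metric),
                na.rm = TRUE)) / (n_perm + 1)
  list(metric = metric, ci = ci, p = p)
}

#' Paired permutation comparison of two models across CV schemes
#'
#' For each repeated scheme, tests the one-sided superiority of model B over
#' model A by randomly swapping the two models' predictions per patient
#' (probability one half) and recomputing the metric difference. The
#' per-scheme p-values are then Benjamini-Hochberg adjusted and the fraction
#' of significant schemes reported. The same exchange scheme applies to AUC
#' and to the C-index, which generalizes the AUC to censored data.
#'
#' @param predsA,predsB Patients x repeats matrices of out-of-fold
#'   predictions of the two models (same patients, same schemes).
#' @param outcome 0/1 labels or [survival::Surv].
#' @param n_perm Swap permutations per scheme (default 100).
#' @param alpha FDR level for the adjusted significance frequency.
#' @param tau Truncation time for Uno's C (survival).
#' @param seed Integer seed.
#' @return List with `p` (per scheme), `p_adjusted`, `significant_frequency`
#'   and `observed_delta` (per-scheme metric differences B - A).
#' @export
paired_permutation_compare <- function(predsA, predsB, outcome,
                                       n_perm = 100L, alpha = 0.05,
                                       tau = NULL, seed = 1L) {
  stopifnot(all(dim(predsA) == dim(predsB)))
  surv <- survival::is.Surv(outcome)
  metric <- function(p) {
    if (surv) uno_cindex(p, outcome[, "time"], outcome[, "status"], tau)
    else roc_auc(p, outcome)
  }
  n <- nrow(predsA); R <- ncol(predsA)
  set.seed(sub_seed(seed, "permutation"))
  pvals <- delta <- numeric(R)
  for (r in seq_len(R)) {
    a <- predsA[, r]; b <- predsB[, r]
    obs <- metric(b) - metric(a)
    null <- vapply(seq_len(n_perm), function(s) {
      swap <- stats::runif(n) < 0.5
      a2 <- ifelse(swap, b, a); b2 <- ifelse(swap, a, b)
      metric(b2) - metric(a2)
    }, numeric(1))
    pvals[r] <- (1 + sum(null >= obs, na.rm = TRUE)) / (n_perm + 1)
    delta[r] <- obs
  }
  adj <- bh_adjust(pvals, alpha)
  list(p = pvals, p_adjusted = adj$adjusted,
       significant_frequency = mean(adj$reject),
       observed_delta = delta)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate procedure.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` (monotone BH-adjusted p-values) and
#'   `reject` (logical, adjusted <= alpha).
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
            alpha > 0, alpha < 1)
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= alpha)
}

#' Performance trend over the number of fused modalities
#'
#' Averages a benchmark metric per modality count and tests adjacent counts
#' with two-sided paired t-tests, pairing the per-scheme averages of the
#' combinations of each count across the repeated CV schemes.
#'
#' @param metrics Combinations x repeats matrix of per-scheme metric values.
#' @param sizes Integer vector: number of modalities of each combination
#'   (row of `metrics`).
#' @return List with `summary` (data frame: count, n_combos, mean, sd) and
#'   `tests` (data frame: count pairs and paired t-test p-values).
#' @export
modality_count_trend <- function(metrics, sizes) {
  stopifnot(nrow(metrics) == length(sizes))
  counts <- sort(unique(sizes))
  per_rep <- t(vapply(counts, function(k) {
    colMeans(metrics[sizes == k, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(metrics))))
  summary <- data.frame(
    count = counts,
    n_combos = vapply(counts, function(k) sum(sizes == k), 0L),
    mean = vapply(counts, function(k)
      mean(metrics[sizes == k, , drop = FALSE], na.rm = TRUE), 0),
    sd = vapply(counts, function(k)
      stats::sd(metrics[sizes == k, , drop = FALSE], na.rm = TRUE), 0))
  tests <- NULL
  if (length(counts) > 1) {
    tests <- data.frame(count_low = counts[-length(counts)],
                        count_high = counts[-1], p = NA_real_)
    for (i in seq_len(nrow(tests))) {
      x <- per_rep[i, ]; y <- per_rep[i + 1, ]
      if (stats::sd(x - y, na.rm = TRUE) > 0)
        tests$p[i] <- stats::t.test(y, x, paired = TRUE)$p.value
    }
  }
  list(summary = summary, tests = tests, per_repeat = per_rep)
}
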