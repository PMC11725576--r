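# Risk stratification for overall survival.
#
# Per CV fold, a cutoff on the training predictions is learned by scanning
# the 30th-70th training percentiles (plus the 0.5 probability threshold for
# classifiers) and keeping the candidate that best separates the training
# survival curves by the log-rank statistic (equivalently, minimizes the
# log-rank p-value, without p underflow). Test patients are assigned
# low/high risk; memberships are aggregated over the repeated schemes by
# majority. Kaplan-Meier / log-rank analyses, quartile stratification of
# averaged scores, and multivariate Cox models with likelihood-ratio tests
# complete the module.

#' Stratification configuration
#'
#' @param percentile_low,percentile_high Bounds of the cutoff search over
#'   training-prediction percentiles (defaults 30 and 70).
#' @param percentile_step Grid step in percentiles (default 1).
#' @param include_half Also consider the 0.5 cutoff for classification
#'   predictions (default `TRUE`).
#' @param alpha FDR level for downstream BH adjustment.
#' @return A `strat_config`.
#' @export
strat_config <- function(percentile_low = 30, percentile_high = 70,
                         percentile_step = 1, include_half = TRUE,
                         alpha = 0.05) {
  stopifnot(percentile_low > 0, percentile_high < 100,
            percentile_low < percentile_high, percentile_step > 0)
  structure(list(percentile_low = percentile_low,
                 percentile_high = percentile_high,
                 percentile_step = percentile_step,
                 include_half = include_half, alpha = alpha),
            class = "strat_config")
}

#' Two-group log-rank test
#'
#' @param groups Two-level group labels.
#' @param time,event Follow-up times and event indicators.
#' @return List with `statistic` (chi-squared, 1 df) and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("log-rank test needs two non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(statistic = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier estimate with Greenwood confidence intervals
#'
#' @param time,event Follow-up times and event indicators.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `time`, `n_risk`, `n_event`, `surv`, `lower`,
#'   `upper`.
#' @export
km_estimate <- function(time, event, conf = 0.95) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf, conf.type = "log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv, lower = fit$lower, upper = fit$upper)
}

#' Learn an optimal risk cutoff on training predictions
#'
#' Candidate cutoffs are the training-prediction percentiles from
#' `percentile_low` to `percentile_high` at the configured step, plus 0.5
#' for classification predictions. The returned cutoff maximizes the
#' training log-rank statistic between the two induced groups (patients
#' strictly above the cutoff are high risk); candidates inducing an empty
#' group or a group without events are skipped. If every candidate is
#' degenerate the median prediction is returned.
#'
#' @param preds Training predictions (probabilities or risk scores).
#' @param time,event Training survival outcome the cutoff is optimized
#'   against (OS for OS-trained models, PFS for PFS-trained ones).
#' @param task `"binary"` or `"survival"` (controls the extra 0.5
#'   candidate).
#' @param cfg A [strat_config()].
#' @return List with `cutoff`, `statistic` and the scanned `candidates`.
#' @export
learn_threshold <- function(preds, time, event,
                            task = c("survival", "binary"),
                            cfg = strat_config()) {
  task <- match.arg(task)
  probs <- seq(cfg$percentile_low, cfg$percentile_high,
               by = cfg$percentile_step) / 100
  cand <- unique(stats::quantile(preds, probs, names = FALSE, type = 7))
  if (task == "binary" && cfg$include_half) cand <- unique(c(cand, 0.5))
  best <- NULL; best_stat <- -Inf
  for (ct in cand) {
    hi <- preds > ct
    if (!any(hi) || all(hi)) next
    if (sum(event[hi]) < 1 || sum(event[!hi]) < 1) next
    st <- logrank_test(hi, time, event)$statistic
    if (st > best_stat) { best_stat <- st; best <- ct }
  }
  if (is.null(best))
    return(list(cutoff = stats::median(preds), statistic = NA_real_,
                candidates = cand, degenerate = TRUE))
  list(cutoff = best, statistic = best_stat, candidates = cand,
       degenerate = FALSE)
}

#' Aggregate risk-group memberships over CV schemes
#'
#' @param membership Logical / 0-1 matrix, patients x schemes (`TRUE` =
#'   high risk; `NA` allowed when a patient had no prediction).
#' @return List with `frequency` (high-risk frequency per patient) and
#'   `group` (`"high"` when the frequency is at least one half — exact ties
#'   are conservatively flagged high risk — else `"low"`).
#' @export
aggregate_membership <- function(membership) {
  membership <- as.matrix(membership)
  freq <- rowMeans(membership, na.rm = TRUE)
  freq[!is.finite(freq)] <- NA_real_
  group <- ifelse(is.na(freq), NA_character_,
                  ifelse(freq >= 0.5, "high", "low"))
  list(frequency = freq, group = group)
}

#' Cross-validated risk-group assignment
#'
#' For every scheme and fold, learns the cutoff on the training predictions
#' and outcome with [learn_threshold()] and assigns the test patients; the
#' per-scheme memberships are aggregated by majority.
#'
#' @param store A [run_benchmark()] prediction store (single-combination
#'   matrices also work: pass the matrix via `preds`).
#' @param preds Patients x repeats matrix of out-of-fold predictions.
#' @param schemes Fold assignments used for the store.
#' @param time,event Survival outcome the thresholds are optimized against.
#' @param task `"binary"` or `"survival"`.
#' @param cfg A [strat_config()].
#' @return The [aggregate_membership()] result plus the per-scheme
#'   membership matrix.
#' @export
cv_risk_groups <- function(preds, schemes, time, event,
                           task = c("survival", "binary"),
                           cfg = strat_config()) {
  task <- match.arg(task)
  n <- nrow(preds)
  membership <- matrix(NA, n, length(schemes))
  for (r in seq_along(schemes)) {
    fold <- schemes[[r]]
    # out-of-fold predictions of repeat r double as training predictions:
    # for fold f, the training patients' predictions come from folds != f of
    # the same scheme, which were produced by models not trained on them.
    for (f in sort(unique(fold))) {
      test <- fold == f
      tr <- !test & !is.na(preds[, r])
      if (sum(event[tr]) < 1) next
      th <- learn_threshold(preds[tr, r], time[tr], event[tr], task, cfg)
      membership[test, r] <- preds[test, r] > th$cutoff
    }
  }
  agg <- aggregate_membership(membership)
  agg$membership <- membership
  agg
}

#' Quartile stratification of an averaged score
#'
#' Splits the cohort into four near-equal groups by rank (ties broken by
#' position, so heavily tied scores still yield balanced groups) and
#' reports the event rate before a horizon per group.
#'
#' @param score Per-patient score (e.g. test predictions averaged across
#'   schemes).
#' @param time,event Survival outcome.
#' @param horizon Horizon in days for the per-group event rate.
#' @return List with `group` (integer 1-4, 4 = highest score) and `summary`
#'   (data frame: group, n, events before horizon, rate).
#' @export
quartile_stratify <- function(score, time, event, horizon = 365) {
  n <- length(score)
  grp <- ceiling(4 * rank(score, ties.method = "first") / n)
  died <- event == 1 & time <= horizon
  summary <- do.call(rbind, lapply(1:4, function(g) {
    idx <- grp == g
    data.frame(group = g, n = sum(idx), events = sum(died[idx]),
               rate = mean(died[idx]))
  }))
  list(group = grp, summary = summary)
}

#' Multivariate Cox model on standardized inputs
#'
#' Standardizes every covariate (zero mean, unit variance), imputes missing
#' covariate cells (median for continuous, most frequent for binary) and
#' missing model scores (0.5 for classification scores, 0 for survival
#' scores), and fits a Cox proportional-hazards model.
#'
#' @param covariates Data frame or matrix of covariates (clinical features
#'   and/or model scores).
#' @param time,event Survival outcome.
#' @param score_cols Names of columns that are model scores; with
#'   `score_task` per column (`"binary"` or `"survival"`) controlling the
#'   missing-score fill-in.
#' @param score_task Named character vector for `score_cols`.
#' @return A `cox_result`: coefficient table (log hazard ratios, 95% CI,
#'   Wald p), log-likelihood, df, n, the fitted model, and a `converged`
#'   flag.
#' @export
fit_cox_multivariate <- function(covariates, time, event,
                                 score_cols = character(0),
                                 score_task = NULL) {
  x <- as.data.frame(covariates)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (nm %in% score_cols) {
      fill <- if (!is.null(score_task) &&
                  identical(score_task[[nm]], "binary")) 0.5 else 0
      v[is.na(v)] <- fill
    } else if (any(is.na(v))) {
      if (is_binary_col(v)) {
        tb <- sort(table(v), decreasing = TRUE)
        v[is.na(v)] <- as.numeric(names(tb))[1]
      } else v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    }
    s <- stats::sd(v)
    x[[nm]] <- if (is.finite(s) && s > 0) (v - mean(v)) / s else v * 0
  }
  df <- cbind(data.frame(.time = time, .status = event), x)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .status) ~ ., data = df),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  coefs <- data.frame(
    covariate = rownames(sm$coefficients),
    log_hr = sm$coefficients[, "coef"],
    se = sm$coefficients[, "se(coef)"],
    lower = sm$coefficients[, "coef"] - 1.96 * sm$coefficients[, "se(coef)"],
    upper = sm$coefficients[, "coef"] + 1.96 * sm$coefficients[, "se(coef)"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 loglik = fit$loglik[2], loglik_null = fit$loglik[1],
                 df = length(stats::coef(fit)), n = fit$n,
                 covariates = names(x), fit = fit,
                 converged = converged),
            class = "cox_result")
}

#' Likelihood-ratio test between nested Cox models
#'
#' `2 * (loglik_full - loglik_reduced)` against a chi-squared distribution
#' with degrees of freedom equal to the parameter-count difference.
#'
#' @param full,reduced Two [fit_cox_multivariate()] results; the reduced
#'   model's covariates must be a subset of the full model's.
#' @return List with `statistic`, `df` and `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "cox_result"), inherits(reduced, "cox_result"))
  if (!all(reduced$covariates %in% full$covariates))
    stop("models are not nested")
  df <- full$df - reduced$df
  if (df <= 0) stop("full model must have more parameters")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
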