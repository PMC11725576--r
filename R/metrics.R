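# Performance metrics: rank-based ROC AUC with tie correction, and Uno's
# inverse-probability-of-censoring-weighted concordance index for censored
# survival data.

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with the usual tie correction: tied
#' score pairs count one half.
#'
#' @param pred Numeric scores (higher = more likely positive).
#' @param labels 0/1 labels; rows with `NA` in either vector are dropped.
#' @return AUC in [0, 1], or `NA` when a class is absent.
#' @export
roc_auc <- function(pred, labels) {
  keep <- !is.na(pred) & !is.na(labels)
  pred <- pred[keep]; y <- as.integer(labels[keep])
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kaplan-Meier estimate of the censoring survival function G(t), evaluated
# left-continuously, G(t-), at arbitrary times.
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- fit$time; ss <- fit$surv
  function(t) {
    # G(t-): survival just before t
    vapply(t, function(ti) {
      idx <- which(tt < ti)
      if (!length(idx)) 1 else ss[max(idx)]
    }, numeric(1))
  }
}

#' Uno's concordance index
#'
#' Censoring-robust concordance using inverse-probability-of-censoring
#' weights from a Kaplan-Meier estimate of the censoring distribution,
#' truncated at `tau`. A pair (i, j) is comparable when patient i has an
#' event at a time earlier than patient j's time and before `tau`; it is
#' weighted by `1 / G(t_i-)^2` and counts fully when the risk scores are
#' concordant (higher risk for the earlier event) and one half on ties.
#'
#' @param pred Risk scores (higher = worse prognosis).
#' @param time,event Follow-up times and event indicators.
#' @param tau Truncation time; defaults to the 95th percentile of observed
#'   follow-up.
#' @return Concordance in [0, 1], or `NA` when no comparable pair exists.
#' @export
uno_cindex <- function(pred, time, event, tau = NULL) {
  keep <- !is.na(pred) & !is.na(time) & !is.na(event)
  pred <- pred[keep]; time <- as.numeric(time[keep])
  event <- as.integer(event[keep])
  n <- length(pred)
  if (n < 2) return(NA_real_)
  if (is.null(tau)) tau <- stats::quantile(time, 0.95, names = FALSE)
  G <- censoring_km(time, event)
  gi <- G(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau) next
    w <- 1 / gi[i]^2
    comp <- time > time[i]
    if (!any(comp)) next
    den <- den + w * sum(comp)
    num <- num + w * (sum(pred[i] > pred[comp]) +
                        0.5 * sum(pred[i] == pred[comp]))
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Unweighted (Harrell-style) concordance fraction used for univariate
# feature screening; ties in score count one half.
harrell_cindex <- function(pred, time, event) {
  uno_weightless(pred, time, event)
}

uno_weightless <- function(pred, time, event) {
  keep <- !is.na(pred) & !is.na(time) & !is.na(event)
  pred <- pred[keep]; time <- as.numeric(time[keep])
  event <- as.integer(event[keep])
  n <- length(pred)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comp <- time > time[i]
    if (!any(comp)) next
    den <- den + sum(comp)
    num <- num + sum(pred[i] > pred[comp]) +
      0.5 * sum(pred[i] == pred[comp])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Univariate score |m - 0.5| of one feature, m = AUC (binary) or
# concordance (survival), used by the early-fusion quota selection.
univariate_metric <- function(feature, outcome, task) {
  if (task == "binary") roc_auc(feature, outcome)
  else harrell_cindex(feature, outcome[, "time"], outcome[, "status"])
}
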