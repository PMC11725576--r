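# Late fusion: average the predictions of independently trained unimodal
# models over the modalities available for each patient. Survival risk
# scores are standardized per modality (mean/sd of inner cross-validated
# training predictions) before averaging; fused boosted-tree classifiers can
# be recalibrated with Platt's logistic map fitted on inner-CV fused
# predictions.

#' Train a late-fusion model
#'
#' Restricts the training set to patients with at least one modality of the
#' combination available, then trains one unimodal model per modality on the
#' patients for whom that modality was collected. For survival specs, a
#' per-modality standardization (mean, sd) is estimated from out-of-fold
#' predictions of an inner 10-fold cross-validation stratified on the event
#' indicator. For boosted-tree classifiers, `calibrate = TRUE` fits a Platt
#' map on inner-CV fused predictions.
#'
#' @param blocks Named list of feature matrices (training rows).
#' @param availability Logical matrix, training rows x modalities.
#' @param outcome 0/1 labels (binary spec) or [survival::Surv] (survival
#'   spec), aligned with the rows.
#' @param combo Character vector of modalities to fuse.
#' @param spec A [learner_spec()]; the same family is used for every
#'   modality.
#' @param calibrate Platt-recalibrate fused boosted-tree probabilities.
#' @param inner_folds Folds of the inner CV used for survival
#'   standardization and calibration.
#' @return A `late_fusion_model`.
#' @export
train_late_fusion <- function(blocks, availability, outcome, combo, spec,
                              calibrate = FALSE, inner_folds = 10L) {
  stopifnot(length(combo) >= 1, !anyDuplicated(combo),
            all(combo %in% colnames(availability)))
  keep <- rowSums(availability[, combo, drop = FALSE]) > 0
  if (spec$task == "binary") keep <- keep & !is.na(outcome)
  blocks <- lapply(blocks, function(b) b[keep, , drop = FALSE])
  availability <- availability[keep, , drop = FALSE]
  outcome <- outcome[keep]

  fitted <- list(); standardize <- list()
  for (k in combo) {
    rows <- availability[, k]
    if (!any(rows)) {
      warning("modality ", k, " has no available training patients; dropped")
      next
    }
    fitted[[k]] <- fit_unimodal(blocks[[k]][rows, , drop = FALSE],
                                outcome[rows], spec)
    if (spec$task == "survival")
      standardize[[k]] <- inner_cv_standardization(
        blocks[[k]][rows, , drop = FALSE], outcome[rows], spec, inner_folds)
  }
  if (!length(fitted)) stop("no modality of the combination is available")

  model <- structure(list(combo = names(fitted), spec = spec,
                          models = fitted, standardize = standardize,
                          calibration = NULL),
                     class = "late_fusion_model")
  if (calibrate && spec$family == "boosted_trees_classifier")
    model$calibration <- late_fusion_platt(model, blocks, availability,
                                           outcome, inner_folds)
  model
}

# Mean/sd of out-of-fold risk predictions from an event-stratified inner CV.
inner_cv_standardization <- function(x, outcome, spec, inner_folds) {
  ev <- as.integer(outcome[, "status"])
  k <- max(2L, min(inner_folds, sum(ev == 1), sum(ev == 0)))
  fold <- stratified_folds(ev, k, seed = spec$seed + 2L)
  oof <- rep(NA_real_, nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(outcome[tr, "status"]) < 1) next
    m <- fit_unimodal(x[tr, , drop = FALSE], outcome[tr], spec)
    oof[!tr] <- predict_unimodal(m, x[!tr, , drop = FALSE])
  }
  mu <- mean(oof, na.rm = TRUE)
  sd_ <- stats::sd(oof, na.rm = TRUE)
  list(mean = if (is.finite(mu)) mu else 0,
       sd = if (is.finite(sd_) && sd_ > 0) sd_ else 1)
}

# Platt map on inner-CV fused classifier predictions.
late_fusion_platt <- function(model, blocks, availability, y, inner_folds) {
  y <- as.integer(y)
  k <- max(2L, min(inner_folds, sum(y == 1), sum(y == 0)))
  fold <- stratified_folds(y, k, seed = model$spec$seed + 3L)
  fused <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    inner <- train_late_fusion(
      lapply(blocks, function(b) b[tr, , drop = FALSE]),
      availability[tr, , drop = FALSE], y[tr], model$combo, model$spec,
      calibrate = FALSE, inner_folds = inner_folds)
    fused[!tr] <- predict_late_fusion(
      inner, lapply(blocks, function(b) b[!tr, , drop = FALSE]),
      availability[!tr, , drop = FALSE])
  }
  ok <- !is.na(fused)
  fit_platt_map(fused[ok], y[ok])
}

#' Predict from a late-fusion model
#'
#' Averages the unimodal predictions over the modalities available for each
#' patient (standardized risk scores for survival specs). Patients with no
#' available modality of the combination receive `NA`.
#'
#' @param model A [train_late_fusion()] result.
#' @param blocks Named list of feature matrices for the rows to predict.
#' @param availability Logical matrix, rows x modalities.
#' @param calibrated Apply the fused Platt map when present.
#' @return Numeric vector of fused predictions.
#' @export
predict_late_fusion <- function(model, blocks, availability,
                                calibrated = TRUE) {
  stopifnot(inherits(model, "late_fusion_model"))
  n <- nrow(availability)
  preds <- matrix(NA_real_, n, length(model$combo),
                  dimnames = list(NULL, model$combo))
  for (k in model$combo) {
    rows <- availability[, k]
    if (!any(rows)) next
    p <- predict_unimodal(model$models[[k]],
                          blocks[[k]][rows, , drop = FALSE])
    if (model$spec$task == "survival") {
      st <- model$standardize[[k]]
      p <- (p - st$mean) / st$sd
    }
    preds[rows, k] <- p
  }
  fused <- rowMeans(preds, na.rm = TRUE)
  fused[rowSums(!is.na(preds)) == 0] <- NA_real_
  if (calibrated && !is.null(model$calibration))
    fused <- stats::plogis(model$calibration$intercept +
                             model$calibration$slope * fused)
  fused
}

#' Fuse per-modality predictions for one or more patients
#'
#' The core late-fusion arithmetic, exposed for reuse: the mean over
#' available (non-`NA`) modality predictions, `NA` when none is available.
#'
#' @param preds Matrix patients x modalities of unimodal predictions
#'   (`NA` where a modality is unavailable).
#' @return Numeric vector of fused predictions.
#' @export
fuse_predictions <- function(preds) {
  preds <- as.matrix(preds)
  out <- rowMeans(preds, na.rm = TRUE)
  out[rowSums(!is.na(preds)) == 0] <- NA_real_
  out
}

#' Modality-level Shapley decomposition of a fused prediction
#'
#' Treats the available modalities as players of the coalition game
#' `v(S) = mean of the unimodal predictions in S`, with `v(empty) = 0.5`
#' (the random-classifier baseline), and returns the exact Shapley value of
#' each modality by enumeration over all coalitions. The efficiency axiom
#' `sum(phi) = v(full) - 0.5` holds exactly.
#'
#' @param preds Named numeric vector of unimodal predictions for one
#'   patient.
#' @param available Logical vector (same names); unavailable modalities get
#'   a zero contribution.
#' @param baseline Value of the empty coalition (default 0.5).
#' @return Named numeric vector of contributions, one per modality.
#' @export
modality_shapley <- function(preds, available = !is.na(preds),
                             baseline = 0.5) {
  mods <- names(preds)
  stopifnot(!is.null(mods), length(available) == length(preds))
  players <- mods[available]
  K <- length(players)
  if (K == 0) stop("no available modality")
  v <- function(S) if (!length(S)) baseline else mean(preds[S])
  phi <- stats::setNames(numeric(length(mods)), mods)
  others <- function(p) setdiff(players, p)
  for (p in players) {
    rest <- others(p)
    for (m in 0:length(rest)) {
      subsets <- if (m == 0) list(character(0)) else
        utils::combn(rest, m, simplify = FALSE)
      w <- factorial(m) * factorial(K - m - 1) / factorial(K)
      for (S in subsets)
        phi[p] <- phi[p] + w * (v(c(S, p)) - v(S))
    }
  }
  phi
}
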