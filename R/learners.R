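# Base learners behind a uniform fit/predict contract.
#
# Four families, two per task:
#   binary:   boosted_trees_classifier (xgboost, native NA handling,
#             positive-class weight = #neg/#pos, Platt-calibratable)
#             penalized_logistic (elastic net, mixing 0.5, inverse
#             regularization strength C = 0.1, balanced class weights)
#   survival: survival_forest (max tree depth 6, risk = total cumulative
#             hazard) and penalized_cox (elastic-net path, minimum
#             regularization ratio 0.01, prediction at the path's end)
# All but the boosted trees see robust scaling (median/IQR) of continuous
# features, median imputation, and most-frequent imputation of binaries,
# fitted on training rows only.

#' Learner specification
#'
#' @param family One of `"boosted_trees_classifier"`, `"penalized_logistic"`
#'   (binary task) or `"survival_forest"`, `"penalized_cox"` (survival task).
#' @param seed Integer seed for any stochastic fitting.
#' @param params Named list of overrides (e.g. `nrounds`, `num.trees`,
#'   `weights`).
#' @return An object of class `learner_spec` with a `task` field.
#' @export
learner_spec <- function(family = c("boosted_trees_classifier",
                                    "penalized_logistic",
                                    "survival_forest", "penalized_cox"),
                         seed = 1L, params = list()) {
  family <- match.arg(family)
  task <- if (family %in% c("boosted_trees_classifier", "penalized_logistic"))
    "binary" else "survival"
  structure(list(family = family, task = task, seed = as.integer(seed),
                 params = params),
            class = "learner_spec")
}

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) > 0 && all(u %in% c(0, 1))
}

#' Fit the robust-scaling / imputation preprocessor
#'
#' Continuous features are centered at the training median and scaled by the
#' training IQR (a degenerate IQR of 0 maps to scale 1), then median-imputed.
#' Binary indicator features are left unscaled and imputed with the most
#' frequent training value.
#'
#' @param x Numeric matrix (training rows only).
#' @param kinds Optional character vector per column, `"continuous"` or
#'   `"categorical"`; auto-detected (values in \{0, 1\}) when `NULL`.
#' @return A `preprocessor` state object.
#' @export
fit_preprocessor <- function(x, kinds = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(kinds))
    kinds <- ifelse(apply(x, 2, is_binary_col), "categorical", "continuous")
  stopifnot(length(kinds) == p)
  center <- scale <- impute <- numeric(p)
  for (j in seq_len(p)) {
    v <- x[, j]
    obs <- v[!is.na(v)]
    if (kinds[j] == "categorical") {
      center[j] <- 0; scale[j] <- 1
      impute[j] <- if (!length(obs)) 0 else
        as.numeric(names(sort(table(obs), decreasing = TRUE))[1])
    } else {
      med <- if (length(obs)) stats::median(obs) else 0
      iqr <- if (length(obs)) stats::IQR(obs, type = 7) else 0
      center[j] <- med
      scale[j] <- if (iqr > 0) iqr else 1
      impute[j] <- 0  # scaled training median
    }
  }
  structure(list(center = center, scale = scale, impute = impute,
                 kinds = kinds, fitted = TRUE, p = p,
                 colnames = colnames(x)),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param state A fitted [fit_preprocessor()] state.
#' @param x Matrix with the same columns as at fit time.
#' @return Scaled and imputed matrix (no `NA` left).
#' @export
apply_preprocessor <- function(state, x) {
  if (!inherits(state, "preprocessor") || !isTRUE(state$fitted))
    stop("preprocessor has not been fitted")
  x <- as.matrix(x)
  stopifnot(ncol(x) == state$p)
  out <- sweep(sweep(x, 2, state$center), 2, state$scale, "/")
  for (j in seq_len(state$p)) {
    na <- is.na(out[, j])
    if (any(na)) out[na, j] <- state$impute[j]
  }
  out
}

balanced_weights <- function(y) {
  n <- length(y)
  tab <- table(factor(y, levels = c(0, 1)))
  w <- n / (2 * tab[as.character(y)])
  as.numeric(w)
}

#' Fit a unimodal base learner
#'
#' @param x Numeric feature matrix (training rows; may contain `NA`).
#' @param outcome For binary specs an integer 0/1 vector; for survival specs
#'   a [survival::Surv] object.
#' @param spec A [learner_spec()].
#' @param preprocess Apply the robust-scaling preprocessor (ignored for
#'   boosted trees, which consume raw features with native `NA` routing).
#' @return A `fitted_model` with `$spec`, learner state, preprocessor state
#'   and (after [platt_calibrate()]) a calibration map.
#' @export
fit_unimodal <- function(x, outcome, spec, preprocess = TRUE) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as.matrix(x)
  model <- list(spec = spec, preproc = NULL, calibration = NULL,
                feature_names = colnames(x))
  set.seed(spec$seed)

  if (spec$task == "binary") {
    y <- as.integer(outcome)
    if (length(unique(y[!is.na(y)])) < 2)
      stop("single-class training labels")
    stopifnot(all(y %in% c(0L, 1L)))
  } else {
    if (!survival::is.Surv(outcome)) stop("survival task needs a Surv outcome")
    if (sum(outcome[, "status"]) < 1) stop("no events in training data")
  }

  if (spec$family == "boosted_trees_classifier") {
    y <- as.integer(outcome)
    spw <- sum(y == 0) / sum(y == 1)
    nrounds <- spec$params$nrounds %||% 100L
    params <- list(objective = "binary:logistic", max_depth = 6,
                   eta = 0.3, scale_pos_weight = spw, nthread = 1)
    dtrain <- xgboost::xgb.DMatrix(data = x, label = y)
    model$fit <- xgboost::xgb.train(params = params, data = dtrain,
                                    nrounds = nrounds, verbose = 0)
  } else if (spec$family == "penalized_logistic") {
    y <- as.integer(outcome)
    if (preprocess) {
      model$preproc <- fit_preprocessor(x)
      x <- apply_preprocessor(model$preproc, x)
    }
    w <- spec$params$weights %||% balanced_weights(y)
    # inverse-regularization strength C = 0.1
    lam <- spec$params$lambda %||% (1 / (0.1 * length(y)))
    model$fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5,
                                lambda = lam, weights = w,
                                standardize = FALSE, maxit = 2500,
                                thresh = spec$params$thresh %||% 1e-7)
  } else if (spec$family == "survival_forest") {
    if (preprocess) {
      model$preproc <- fit_preprocessor(x)
      x <- apply_preprocessor(model$preproc, x)
    }
    df <- as.data.frame(x)
    names(df) <- paste0("V", seq_len(ncol(df)))
    df$.time <- as.numeric(outcome[, "time"])
    df$.status <- as.integer(outcome[, "status"])
    model$fit <- ranger::ranger(
      survival::Surv(.time, .status) ~ ., data = df,
      num.trees = spec$params$num.trees %||% 500L,
      max.depth = 6, seed = spec$seed, num.threads = 1)
  } else { # penalized_cox
    if (preprocess) {
      model$preproc <- fit_preprocessor(x)
      x <- apply_preprocessor(model$preproc, x)
    }
    fit <- glmnet::glmnet(x, outcome, family = "cox", alpha = 0.5,
                          nlambda = 100, lambda.min.ratio = 0.01,
                          standardize = FALSE)
    model$fit <- fit
    model$lambda <- min(fit$lambda)
  }
  class(model) <- "fitted_model"
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted base learner
#'
#' @param model A [fit_unimodal()] result.
#' @param x Feature matrix for the rows to predict.
#' @param calibrated Apply the Platt map when present.
#' @return For binary specs a probability in (0, 1) (raw boosted-tree /
#'   logistic probability, or the Platt-mapped version); for survival specs
#'   a real risk score (higher = worse prognosis).
#' @export
predict_unimodal <- function(model, x, calibrated = TRUE) {
  stopifnot(inherits(model, "fitted_model"))
  x <- as.matrix(x)
  spec <- model$spec
  if (!is.null(model$preproc)) x <- apply_preprocessor(model$preproc, x)
  raw <- if (spec$family == "boosted_trees_classifier") {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(data = x)))
  } else if (spec$family == "penalized_logistic") {
    as.numeric(stats::predict(model$fit, x, type = "response"))
  } else if (spec$family == "survival_forest") {
    df <- as.data.frame(x)
    names(df) <- paste0("V", seq_len(ncol(df)))
    chf <- stats::predict(model$fit, data = df, num.threads = 1)$chf
    rowSums(chf)   # aggregate cumulative hazard, as survival-forest risk
  } else {
    as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                              type = "link"))
  }
  if (calibrated && !is.null(model$calibration))
    raw <- stats::plogis(model$calibration$intercept +
                           model$calibration$slope * raw)
  raw
}

# Stratified fold assignment: within each stratum, shuffled round-robin so
# per-fold stratum counts differ by at most one patient.
stratified_folds <- function(strata, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(strata)
  fold <- integer(n)
  start <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    start <- start + length(idx)
  }
  fold
}

#' Platt probability calibration
#'
#' Collects out-of-fold raw predictions by refitting the learner within a
#' stratified inner cross-validation of the training set, fits a univariate
#' logistic map with balanced class weights, and attaches it to the model.
#' When a class has fewer members than `inner_folds`, the fold count is
#' reduced so every inner training part contains both classes.
#'
#' @param model A fitted binary `fitted_model`.
#' @param x,y Training features and 0/1 labels (the same data the model was
#'   fitted on).
#' @param inner_folds Number of inner folds (default 10).
#' @return The model with a `$calibration` map applied by
#'   [predict_unimodal()].
#' @export
platt_calibrate <- function(model, x, y, inner_folds = 10L) {
  stopifnot(inherits(model, "fitted_model"), model$spec$task == "binary")
  x <- as.matrix(x); y <- as.integer(y)
  k <- max(2L, min(inner_folds, sum(y == 1), sum(y == 0)))
  fold <- stratified_folds(y, k, seed = model$spec$seed + 1L)
  raw <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    inner <- fit_unimodal(x[tr, , drop = FALSE], y[tr], model$spec)
    raw[!tr] <- predict_unimodal(inner, x[!tr, , drop = FALSE],
                                 calibrated = FALSE)
  }
  model$calibration <- fit_platt_map(raw, y)
  model
}

# One-variable logistic map fitted on held-out scores with balanced weights.
fit_platt_map <- function(raw, y) {
  w <- balanced_weights(y)
  fit <- suppressWarnings(
    stats::glm(y ~ raw, family = stats::binomial(), weights = w))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}
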