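# Model-agnostic Shapley attributions.
#
# The value of a feature coalition S for a patient x is the expected model
# output when the features in S take the patient's values and the remaining
# features are marginalized over a background sample:
#   v(S) = mean_b f(x_S, background_b_rest).
# Attributions are exact (subset enumeration with Shapley weights) when the
# feature count is small, and otherwise estimated with antithetic
# permutation sampling: each sampled feature order is walked forward and
# backward, crediting each feature with its marginal change in v. Both modes
# satisfy local accuracy: attributions sum to f(x) - v(empty set).

#' Shapley attributions for a prediction function
#'
#' @param predict_fun Function taking a feature matrix and returning a
#'   numeric prediction per row.
#' @param x Feature matrix of the rows to explain (e.g. the test rows of a
#'   CV fold).
#' @param background Feature matrix used to marginalize absent features
#'   (typically the training rows).
#' @param exact_limit Use exact subset enumeration when `ncol(x)` is at most
#'   this (default 10).
#' @param n_perm Sampled permutations per row in the sampling regime
#'   (each is also walked in reverse; default 10).
#' @param seed Integer seed for the sampling regime.
#' @return List with `attributions` (matrix like `x`) and `baseline`
#'   (`v(empty)`, the mean background prediction).
#' @export
shap_attributions <- function(predict_fun, x, background,
                              exact_limit = 10L, n_perm = 10L, seed = 1L) {
  x <- as.matrix(x); background <- as.matrix(background)
  p <- ncol(x)
  stopifnot(ncol(background) == p)
  baseline <- mean(predict_fun(background))
  attr <- if (p <= exact_limit)
    shap_exact(predict_fun, x, background, baseline)
  else shap_sampling(predict_fun, x, background, n_perm, seed)
  dimnames(attr) <- dimnames(x)
  list(attributions = attr, baseline = baseline)
}

# v(S) for one row: mean prediction over background rows with columns S
# overwritten by the row's values.
coalition_value <- function(predict_fun, row, background, S) {
  masked <- background
  if (length(S)) masked[, S] <- matrix(row[S], nrow(background),
                                       length(S), byrow = TRUE)
  mean(predict_fun(masked))
}

shap_exact <- function(predict_fun, x, background, baseline) {
  p <- ncol(x); n <- nrow(x)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  sizes <- 0:(p - 1)   # coalition sizes excluding the explained feature
  w_tab <- factorial(sizes) * factorial(p - sizes - 1) / factorial(p)
  attr <- matrix(0, n, p)
  for (i in seq_len(n)) {
    vals <- vapply(subsets, function(S)
      coalition_value(predict_fun, x[i, ], background, S), numeric(1))
    names(vals) <- vapply(subsets, function(S)
      paste(S, collapse = ","), "")
    for (j in seq_len(p)) {
      for (si in seq_along(subsets)) {
        S <- subsets[[si]]
        if (j %in% S) next
        key_with <- paste(sort(c(S, j)), collapse = ",")
        attr[i, j] <- attr[i, j] +
          w_tab[length(S) + 1] * (vals[[key_with]] - vals[[si]])
      }
    }
  }
  attr
}

shap_sampling <- function(predict_fun, x, background, n_perm, seed) {
  p <- ncol(x); n <- nrow(x)
  set.seed(as.integer(seed))
  attr <- matrix(0, n, p)
  for (i in seq_len(n)) {
    acc <- numeric(p)
    for (s in seq_len(n_perm)) {
      ord <- sample.int(p)
      for (o in list(ord, rev(ord))) {
        prev <- coalition_value(predict_fun, x[i, ], background,
                                integer(0))
        S <- integer(0)
        for (j in o) {
          S <- c(S, j)
          cur <- coalition_value(predict_fun, x[i, ], background, S)
          acc[j] <- acc[j] + (cur - prev)
          prev <- cur
        }
      }
    }
    attr[i, ] <- acc / (2 * n_perm)
  }
  attr
}

#' Shapley attributions across a cross-validated benchmark
#'
#' For each repeated scheme, refits the model per fold on the training rows
#' and attributes the predictions of the test rows only; matrices are then
#' averaged element-wise over schemes.
#'
#' @param fit_fun Function `(x, outcome) -> model`.
#' @param pred_fun Function `(model, x) -> predictions`.
#' @param x Feature matrix (full cohort rows for one modality).
#' @param outcome Outcome vector / [survival::Surv] aligned with `x`.
#' @param schemes List of fold assignments ([make_cv_schemes()]).
#' @param ... Passed to [shap_attributions()].
#' @return List with `mean_attributions` (patients x features) and
#'   `per_scheme` (list of matrices).
#' @export
cv_shap_attributions <- function(fit_fun, pred_fun, x, outcome, schemes,
                                 ...) {
  labeled <- if (survival::is.Surv(outcome)) rep(TRUE, nrow(x))
  else !is.na(outcome)
  per_scheme <- lapply(schemes, function(fold) {
    attr <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
    for (f in sort(unique(fold))) {
      test <- fold == f
      tr <- !test & labeled
      model <- fit_fun(x[tr, , drop = FALSE],
                       if (survival::is.Surv(outcome)) outcome[tr, ]
                       else outcome[tr])
      sh <- shap_attributions(function(m) pred_fun(model, m),
                              x[test, , drop = FALSE],
                              x[tr, , drop = FALSE], ...)
      attr[test, ] <- sh$attributions
    }
    attr
  })
  list(mean_attributions = average_attributions(per_scheme),
       per_scheme = per_scheme)
}

#' Element-wise mean of per-scheme attribution matrices
#'
#' @param matrices List of equally shaped matrices.
#' @return The element-wise mean matrix (`NA` cells ignored).
#' @export
average_attributions <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  d <- dim(matrices[[1]])
  ok <- vapply(matrices, function(m) all(dim(m) == d), TRUE)
  if (!all(ok)) stop("attribution matrices have mismatched shapes")
  arr <- array(unlist(matrices), dim = c(d, length(matrices)))
  out <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  dimnames(out) <- dimnames(matrices[[1]])
  out
}
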