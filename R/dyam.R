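# Dynamic attention with masking (DyAM): a multimodal classifier in which
# each modality k contributes a score head u_k = tanh(affine(x_k)) and an
# attention head a_k = softplus(affine(x_k)) > 0. Unavailable modalities are
# masked out; the output probability is
#   sigma( sum_{k available} (a_k / sum a) * u_k ).
# Trained full-batch with class-weighted binary cross-entropy, Adam, a fixed
# learning rate / epoch count, and L2 regularization added to the gradient
# (weight-decay convention). Implemented directly in R with hand-derived
# gradients; the model is small (one affine pair per modality).

#' DyAM configuration
#'
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs Training epochs, full batch (default 125).
#' @param l2 L2 regularization strength (default 0.001).
#' @param pca_components Principal components for the high-dimensional
#'   pathomics block (default 40).
#' @param pca_modality Modality the PCA step applies to.
#' @param grid_lr,grid_l2 Nested-CV grids for [dyam_grid_search()].
#' @param seed Integer seed (weight initialization).
#' @return A `dyam_config`.
#' @export
dyam_config <- function(learning_rate = 0.01, epochs = 125L, l2 = 0.001,
                        pca_components = 40L, pca_modality = "pathomics",
                        grid_lr = c(0.1, 0.01, 0.001),
                        grid_l2 = c(0.01, 0.001, 1e-4),
                        seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, l2 >= 0, pca_components >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 l2 = l2, pca_components = as.integer(pca_components),
                 pca_modality = pca_modality, grid_lr = grid_lr,
                 grid_l2 = grid_l2, seed = as.integer(seed)),
            class = "dyam_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Preprocess blocks for DyAM: robust scaling + imputation per modality on
# available training rows, PCA reduction of the designated modality.
dyam_preprocess_fit <- function(blocks, availability, combo, cfg,
                                selected) {
  prep <- list()
  for (k in combo) {
    rows <- availability[, k]
    b <- blocks[[k]][rows, selected[[k]], drop = FALSE]
    pp <- fit_preprocessor(b)
    pca <- NULL
    if (identical(k, cfg$pca_modality)) {
      z <- apply_preprocessor(pp, b)
      ncomp <- min(cfg$pca_components, ncol(z), sum(rows) - 1L)
      pca <- stats::prcomp(z, center = TRUE, rank. = ncomp)
      pca <- list(center = pca$center, rotation = pca$rotation)
    }
    prep[[k]] <- list(pp = pp, pca = pca, features = selected[[k]])
  }
  prep
}

dyam_transform <- function(prep, blocks, availability, combo) {
  xs <- list()
  for (k in combo) {
    b <- blocks[[k]][, prep[[k]]$features, drop = FALSE]
    z <- matrix(0, nrow(b), ncol(b))
    av <- availability[, k]
    if (any(av))
      z[av, ] <- apply_preprocessor(prep[[k]]$pp, b[av, , drop = FALSE])
    if (!is.null(prep[[k]]$pca)) {
      pc <- prep[[k]]$pca
      z <- sweep(z, 2, pc$center) %*% pc$rotation
    }
    xs[[k]] <- z
  }
  xs
}

# Forward pass; returns intermediates needed by the backward pass.
dyam_forward <- function(params, xs, avail, combo) {
  n <- nrow(avail)
  U <- G <- A <- matrix(0, n, length(combo),
                        dimnames = list(NULL, combo))
  for (k in combo) {
    th <- params[[k]]
    h <- drop(xs[[k]] %*% th$w) + th$b
    g <- drop(xs[[k]] %*% th$v) + th$c
    U[, k] <- tanh(h)
    G[, k] <- g
    A[, k] <- softplus(g)
  }
  A[!avail[, combo, drop = FALSE]] <- 0
  S <- rowSums(A)
  Abar <- A / ifelse(S > 0, S, 1)
  z <- rowSums(Abar * U * (avail[, combo, drop = FALSE] + 0))
  p <- stats::plogis(z)
  list(U = U, G = G, A = A, S = S, Abar = Abar, z = z, p = p)
}

#' Train a DyAM model
#'
#' @param blocks Named list of feature matrices (training rows).
#' @param availability Logical matrix, rows x modalities.
#' @param labels 0/1 labels.
#' @param combo Modalities to combine.
#' @param cfg A [dyam_config()].
#' @param selection Optional [selection_config()] applied before training.
#' @return A `dyam_model`.
#' @export
train_dyam <- function(blocks, availability, labels, combo,
                       cfg = dyam_config(), selection = NULL) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0:1, NA)), length(combo) >= 1)
  keep <- rowSums(availability[, combo, drop = FALSE]) > 0 & !is.na(y)
  blocks <- lapply(blocks, function(b) b[keep, , drop = FALSE])
  availability <- availability[keep, , drop = FALSE]
  y <- y[keep]

  selected <- if (is.null(selection))
    stats::setNames(lapply(combo, function(k) colnames(blocks[[k]])), combo)
  else select_features(blocks, availability, y, combo, selection,
                       task = "binary")
  prep <- dyam_preprocess_fit(blocks, availability, combo, cfg, selected)
  xs <- dyam_transform(prep, blocks, availability, combo)
  avail <- availability[, combo, drop = FALSE]

  # per-modality init seeds derive from the modality name, so a model is
  # invariant to the order in which the combination lists its modalities
  params <- lapply(combo, function(k) {
    set.seed(cfg$seed + sum(utf8ToInt(k)))
    p <- ncol(xs[[k]])
    list(w = stats::rnorm(p, sd = 0.1), b = 0,
         v = stats::rnorm(p, sd = 0.1), c = 0)
  })
  names(params) <- combo

  wts <- balanced_weights(y)
  n <- length(y)
  adam <- lapply(params, function(th)
    lapply(th, function(x) list(m = x * 0, v = x * 0)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0

  for (epoch in seq_len(cfg$epochs)) {
    fw <- dyam_forward(params, xs, avail, combo)
    dz <- wts * (fw$p - y) / n
    grads <- list()
    for (k in combo) {
      av <- avail[, k]
      du <- dz * fw$Abar[, k] * (1 - fw$U[, k]^2)
      dg <- dz * ((fw$U[, k] - fw$z) / ifelse(fw$S > 0, fw$S, 1)) *
        stats::plogis(fw$G[, k])
      du[!av] <- 0; dg[!av] <- 0
      th <- params[[k]]
      grads[[k]] <- list(
        w = drop(crossprod(xs[[k]], du)) + cfg$l2 * th$w,
        b = sum(du) + cfg$l2 * th$b,
        v = drop(crossprod(xs[[k]], dg)) + cfg$l2 * th$v,
        c = sum(dg) + cfg$l2 * th$c)
    }
    t <- t + 1
    for (k in combo) for (nm in names(params[[k]])) {
      g <- grads[[k]][[nm]]
      st <- adam[[k]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      adam[[k]][[nm]] <- st
      mhat <- st$m / (1 - b1^t); vhat <- st$v / (1 - b2^t)
      params[[k]][[nm]] <- params[[k]][[nm]] -
        cfg$learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(combo = combo, cfg = cfg, params = params, prep = prep,
                 selected = selected),
            class = "dyam_model")
}

#' Predict from a DyAM model
#'
#' @param model A [train_dyam()] result.
#' @param blocks Named list of feature matrices for the rows to predict.
#' @param availability Logical matrix, rows x modalities.
#' @param details Also return the per-modality scores and normalized
#'   attention weights.
#' @return Probabilities (`NA` for patients with no available modality), or
#'   a list with `prob`, `scores`, `attention` when `details = TRUE`.
#' @export
predict_dyam <- function(model, blocks, availability, details = FALSE) {
  stopifnot(inherits(model, "dyam_model"))
  xs <- dyam_transform(model$prep, blocks, availability, model$combo)
  avail <- availability[, model$combo, drop = FALSE]
  fw <- dyam_forward(model$params, xs, avail, model$combo)
  prob <- fw$p
  prob[rowSums(avail) == 0] <- NA_real_
  if (!details) return(prob)
  list(prob = prob, scores = fw$U, attention = fw$Abar)
}

#' Nested grid search over DyAM learning rate and L2 strength
#'
#' Inner stratified cross-validation on the training set, scored by ROC AUC
#' of out-of-fold predictions; the best (learning rate, L2) pair is refitted
#' on the full training set.
#'
#' @inheritParams train_dyam
#' @param inner_folds Inner folds (default 10).
#' @return The refitted `dyam_model`, with `$grid` (the scored grid) and
#'   `$best` attached.
#' @export
dyam_grid_search <- function(blocks, availability, labels, combo,
                             cfg = dyam_config(), selection = NULL,
                             inner_folds = 10L) {
  y <- as.integer(labels)
  k <- max(2L, min(inner_folds, sum(y == 1), sum(y == 0)))
  fold <- stratified_folds(y, k, seed = cfg$seed + 4L)
  grid <- expand.grid(lr = cfg$grid_lr, l2 = cfg$grid_l2)
  grid$auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cg <- cfg; cg$learning_rate <- grid$lr[g]; cg$l2 <- grid$l2[g]
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- train_dyam(lapply(blocks, function(b) b[tr, , drop = FALSE]),
                      availability[tr, , drop = FALSE], y[tr], combo, cg,
                      selection)
      oof[!tr] <- predict_dyam(
        m, lapply(blocks, function(b) b[!tr, , drop = FALSE]),
        availability[!tr, , drop = FALSE])
    }
    grid$auc[g] <- roc_auc(oof, y)
  }
  best <- grid[which.max(grid$auc), ]
  cfg$learning_rate <- best$lr; cfg$l2 <- best$l2
  model <- train_dyam(blocks, availability, y, combo, cfg, selection)
  model$grid <- grid
  model$best <- best
  model
}
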