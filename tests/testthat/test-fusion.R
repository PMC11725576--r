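test_that("fused classifier probabilities are the mean over available
           modalities", {
  expect_equal(fuse_predictions(cbind(0.2, 0.6)), 0.4)
  expect_equal(fuse_predictions(cbind(c(0.2, NA), c(0.6, 0.8),
                                      c(0.4, 0.2))),
               c(0.4, 0.5))
  expect_true(is.na(fuse_predictions(cbind(NA_real_, NA_real_))))
  # fusing a model with itself is the model
  p <- runif(10)
  expect_equal(fuse_predictions(cbind(p, p)), p)
})

test_that("a single-modality late fusion equals the unimodal model", {
  co <- small_cohort(seed = 20)
  y <- co$outcomes$label_1y_death
  bl <- co$data$blocks; av <- co$data$availability
  spec <- learner_spec("penalized_logistic")
  lf <- train_late_fusion(bl, av, y, "rna", spec)
  keep <- !is.na(y)
  uni <- fit_unimodal(bl$rna[keep, ], y[keep], spec)
  expect_equal(predict_late_fusion(lf, bl, av),
               predict_unimodal(uni, bl$rna))
})

test_that("survival late fusion equals the standardize-then-average oracle", {
  co <- small_cohort(seed = 21)
  surv <- survival::Surv(co$outcomes$os_time, co$outcomes$os_event)
  bl <- co$data$blocks; av <- co$data$availability
  spec <- learner_spec("penalized_cox")
  lf <- train_late_fusion(bl, av, surv, c("clinical", "rna"), spec,
                          inner_folds = 3)
  got <- predict_late_fusion(lf, bl, av)
  manual <- sapply(c("clinical", "rna"), function(k) {
    p <- predict_unimodal(lf$models[[k]], bl[[k]])
    (p - lf$standardize[[k]]$mean) / lf$standardize[[k]]$sd
  })
  expect_equal(got, rowMeans(manual), tolerance = 1e-12)
  # the pure arithmetic of the spec example
  expect_equal(fuse_predictions(cbind(1.0, -0.5)), 0.25)
})

test_that("late fusion predicts any patient with at least one modality", {
  co <- small_cohort(n = 120, seed = 22)
  y <- co$outcomes$label_1y_death
  bl <- co$data$blocks
  av <- co$data$availability
  av[1:30, "rna"] <- FALSE
  av[10:20, "clinical"] <- FALSE   # patients 10:20 keep nothing of the combo
  lf <- train_late_fusion(bl, av, y, c("clinical", "rna"),
                          learner_spec("penalized_logistic"))
  p <- predict_late_fusion(lf, bl, av)
  expect_true(all(is.na(p[10:20])))
  expect_true(all(!is.na(p[21:30])))
  # patients missing rna get exactly the clinical unimodal prediction
  p_clin <- predict_unimodal(lf$models$clinical, bl$clinical)
  expect_equal(p[21:30], p_clin[21:30])
})

test_that("quota feature selection matches the hand-derived result", {
  set.seed(30)
  n <- 400
  y <- rep(c(0L, 1L), n / 2)
  # block A: a1 strong, a2 = exact duplicate of a1 (r = 1), a3 weak, a4 noise
  a1 <- y + rnorm(n, sd = 0.5)
  a3 <- y + rnorm(n, sd = 2.5)
  A <- cbind(a1 = a1, a2 = a1, a3 = a3, a4 = rnorm(n))
  # block B: b1 medium, b2 noise
  B <- cbind(b1 = y + rnorm(n, sd = 1.2), b2 = rnorm(n))
  blocks <- list(A = A, B = B)
  av <- cbind(A = rep(TRUE, n), B = rep(TRUE, n))
  sel <- select_features(blocks, av, y, c("A", "B"),
                         selection_config(n_total = 4, rho = 0.7),
                         task = "binary")
  # quota = floor(4/2) = 2 per modality; duplicate a2 removed by the
  # correlation filter, so A keeps its strongest non-redundant pair
  expect_equal(sel$A, c("a1", "a3"))
  expect_equal(sel$B, c("b1", "b2"))
  # unimodal combinations bypass selection entirely
  uni <- select_features(blocks, av, y, "A",
                         selection_config(n_total = 2), task = "binary")
  expect_equal(uni$A, colnames(A))
  # budget is never exceeded
  expect_lte(length(unlist(sel)), 4L)
})

test_that("double coding emits sentinel pairs for missing modalities", {
  b <- cbind(f1 = c(0.5, 0.2), f2 = c(-1, 3))
  av <- c(TRUE, FALSE)
  dc <- double_code(b, av)
  expect_equal(ncol(dc), 4L)
  expect_equal(unname(dc[1, ]), c(0.5, -1, 0.5, -1))
  expect_equal(unname(dc[2, ]), c(1e6, 1e6, -1e6, -1e6))
})

test_that("early fusion zero-fills missing modalities for linear models", {
  co <- small_cohort(n = 120, seed = 23)
  y <- co$outcomes$label_1y_death
  bl <- co$data$blocks
  av <- co$data$availability
  av[1:20, "rna"] <- FALSE
  ef <- train_early_fusion(bl, av, y, c("clinical", "rna"),
                           learner_spec("penalized_logistic"))
  xx <- immunofuse:::assemble_early_matrix(ef, bl, av)
  rna_cols <- grep("^rna\\.", colnames(xx))
  expect_true(all(xx[1:20, rna_cols] == 0))
  expect_false(all(xx[21, rna_cols] == 0))
  # width is the sum of the selected block widths
  expect_equal(ncol(xx), ncol(bl$clinical) + ncol(bl$rna))
})

test_that("early fusion double-codes blocks for survival forests", {
  co <- small_cohort(n = 100, seed = 24)
  surv <- survival::Surv(co$outcomes$os_time, co$outcomes$os_event)
  bl <- co$data$blocks
  av <- co$data$availability
  av[1:10, "rna"] <- FALSE
  ef <- train_early_fusion(bl, av, surv, c("clinical", "rna"),
                           learner_spec("survival_forest"))
  xx <- immunofuse:::assemble_early_matrix(ef, bl, av)
  expect_equal(ncol(xx), 2 * (ncol(bl$clinical) + ncol(bl$rna)))
  expect_true(all(xx[1:10, grep("^rna\\..*_hi$", colnames(xx))] == 1e6))
  expect_true(all(xx[1:10, grep("^rna\\..*_lo$", colnames(xx))] == -1e6))
  p <- predict_early_fusion(ef, bl, av)
  expect_false(anyNA(p))
})

test_that("early fusion of disjoint signals beats each single block", {
  co <- small_cohort(n = 400, betas = c(clinical = 0.9, radiomics = 0,
                                        pathomics = 0, rna = 0.9),
                     seed = 25)
  y <- co$outcomes$label_1y_death
  keep <- which(!is.na(y))
  tr <- keep[seq_len(250)]; te <- setdiff(keep, tr)
  bl <- co$data$blocks; av <- co$data$availability
  spec <- learner_spec("penalized_logistic")
  sub <- function(i) lapply(bl, function(b) b[i, , drop = FALSE])
  ef <- train_early_fusion(sub(tr), av[tr, ], y[tr],
                           c("clinical", "rna"), spec)
  auc_fused <- roc_auc(predict_early_fusion(ef, sub(te), av[te, ]), y[te])
  auc_uni <- sapply(c("clinical", "rna"), function(k) {
    m <- fit_unimodal(bl[[k]][tr, ], y[tr], spec)
    roc_auc(predict_unimodal(m, bl[[k]][te, ]), y[te])
  })
  expect_gt(auc_fused, max(auc_uni))
})

test_that("modality Shapley values match coalition enumeration", {
  phi <- modality_shapley(c(A = 0.9, B = 0.5))
  expect_equal(unname(phi), c(0.3, -0.1))
  # symmetry: identical predictions share the credit equally
  phi4 <- modality_shapley(c(a = 0.8, b = 0.8, c = 0.8, d = 0.8))
  expect_equal(unname(phi4), rep(0.3 / 4, 4))
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    preds <- stats::setNames(runif(k), letters[seq_len(k)])
    phi <- modality_shapley(preds)
    # efficiency: contributions add up to the fused lift over 0.5
    expect_equal(sum(phi), mean(preds) - 0.5, tolerance = 1e-12)
    # agreement with the permutation-enumeration oracle
    expect_equal(phi, brute_shapley(preds), tolerance = 1e-12)
  }
  # unavailable modalities contribute nothing
  phi_m <- modality_shapley(c(A = 0.9, B = 0.5, C = 0.2),
                            available = c(TRUE, TRUE, FALSE))
  expect_equal(unname(phi_m["C"]), 0)
  expect_equal(sum(phi_m), mean(c(0.9, 0.5)) - 0.5, tolerance = 1e-12)
  expect_error(modality_shapley(c(A = 1), available = FALSE), "available")
})
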