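test_that("stratified schemes balance folds and strata", {
  set.seed(70)
  y <- rbinom(83, 1, 0.3)
  schemes <- make_cv_schemes(y, n_repeats = 5, n_folds = 10, seed = 1)
  for (fold in schemes) {
    sizes <- table(fold)
    expect_lte(max(sizes) - min(sizes), 1)
    # per-fold positives within one patient of a proportional share
    pos_per_fold <- tapply(y, fold, sum)
    expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  }
  # identical schemes across models under the same master seed
  again <- make_cv_schemes(y, n_repeats = 5, n_folds = 10, seed = 1)
  expect_identical(schemes, again)
  other <- make_cv_schemes(y, n_repeats = 5, n_folds = 10, seed = 2)
  expect_false(identical(schemes, other))
})

make_benchmark_fixture <- function(n = 90, seed = 71) {
  co <- small_cohort(n = n, seed = seed)
  surv <- survival::Surv(co$outcomes$os_time, co$outcomes$os_event)
  schemes <- make_cv_schemes(co$outcomes$os_event, n_repeats = 2,
                             n_folds = 5, seed = 8)
  list(co = co, surv = surv, schemes = schemes)
}

test_that("every patient is predicted exactly once per repeat", {
  f <- make_benchmark_fixture()
  st <- run_benchmark(f$co$data$blocks, f$co$data$availability, f$surv,
                      learner_spec("penalized_cox"),
                      combos = list("clinical", c("clinical", "rna")),
                      schemes = f$schemes, strategy = "late",
                      inner_folds = 2)
  for (id in st$combo_ids) {
    expect_false(anyNA(st$preds[[id]]))
    expect_equal(dim(st$preds[[id]]), c(90L, 2L))
  }
})

test_that("the benchmark is deterministic under a fixed master seed", {
  f <- make_benchmark_fixture()
  run <- function() run_benchmark(
    f$co$data$blocks, f$co$data$availability, f$surv,
    learner_spec("penalized_cox"), combos = list(c("clinical", "rna")),
    schemes = f$schemes, strategy = "late", inner_folds = 2)
  expect_identical(run()$preds, run()$preds)
})

test_that("patients missing all combo modalities get NA but keep other
           predictions", {
  f <- make_benchmark_fixture()
  av <- f$co$data$availability
  av[1:8, "rna"] <- FALSE
  st <- run_benchmark(f$co$data$blocks, av, f$surv,
                      learner_spec("penalized_cox"),
                      combos = list("rna", c("clinical", "rna")),
                      schemes = f$schemes, strategy = "late",
                      inner_folds = 2)
  expect_true(all(is.na(st$preds[["rna"]][1:8, ])))
  expect_false(anyNA(st$preds[["rna"]][9:90, ]))
  # late fusion still defines a prediction through the clinical block
  expect_false(anyNA(st$preds[["clinical+rna"]]))
})

test_that("binary benchmarks skip excluded labels in training but predict
           everyone", {
  f <- make_benchmark_fixture(n = 120, seed = 72)
  y <- f$co$outcomes$label_1y_death
  schemes <- make_cv_schemes(y, n_repeats = 2, n_folds = 5, seed = 3)
  st <- run_benchmark(f$co$data$blocks, f$co$data$availability, y,
                      learner_spec("penalized_logistic"),
                      combos = list(c("clinical", "rna")),
                      schemes = schemes, strategy = "late")
  expect_false(anyNA(st$preds[[1]]))
})

test_that("restricted evaluation reduces to per-repeat metric summaries", {
  # hand-built store: 3 repeats, 6 patients, known AUCs
  y <- c(0, 0, 0, 1, 1, 1)
  p1 <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)   # AUC 1
  p2 <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)   # AUC 0
  p3 <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)   # AUC 0.5
  store <- structure(list(task = "binary",
                          combos = list("m"), combo_ids = "m",
                          preds = list(m = cbind(p1, p2, p3)),
                          n_repeats = 3L),
                     class = "prediction_store")
  ev <- evaluate_restricted(store, "m", y)
  expect_equal(ev$per_repeat, c(p1 = 1, p2 = 0, p3 = 0.5),
               ignore_attr = TRUE)
  expect_equal(ev$mean, 0.5)
  expect_equal(ev$sd, sd(c(1, 0, 0.5)))
  # restricting to a subset changes the pooled predictions scored
  ev_sub <- evaluate_restricted(store, "m", y, subset = c(1, 2, 4, 5))
  expect_equal(ev_sub$per_repeat[[1]], 1)
  # a single-class subset is NA
  expect_true(all(is.na(
    evaluate_restricted(store, "m", y, subset = 1:3)$per_repeat)))
})

test_that("early-fusion and DyAM benchmarks produce complete stores", {
  co <- small_cohort(n = 80, seed = 73)
  y <- co$outcomes$label_1y_death
  schemes <- make_cv_schemes(y, n_repeats = 1, n_folds = 4, seed = 4)
  st_e <- run_benchmark(co$data$blocks, co$data$availability, y,
                        learner_spec("penalized_logistic"),
                        combos = list(c("clinical", "rna")),
                        schemes = schemes, strategy = "early",
                        selection = selection_config(n_total = 8))
  expect_false(anyNA(st_e$preds[[1]]))
  st_d <- run_benchmark(co$data$blocks, co$data$availability, y,
                        learner_spec("penalized_logistic"),
                        combos = list(c("clinical", "rna")),
                        schemes = schemes, strategy = "dyam",
                        dyam_cfg = dyam_config(epochs = 15,
                                               pca_modality = "none"))
  expect_false(anyNA(st_d$preds[[1]]))
  expect_true(all(st_d$preds[[1]] > 0 & st_d$preds[[1]] < 1))
})
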