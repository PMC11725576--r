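test_that("default cohort reproduces the emulated schema", {
  co <- generate_cohort(cohort_config(seed = 3))
  expect_equal(length(co$data$patient_ids), 317L)
  expect_equal(unname(vapply(co$data$blocks, ncol, 0L)),
               c(30L, 30L, 134L, 34L))
  expect_equal(unname(colSums(co$data$availability)),
               c(317L, 201L, 236L, 134L))
  expect_equal(length(complete_profile_ids(co$data)), 80L)
})

test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(cohort_config(n_patients = 60, seed = 5,
                                     missingness = NULL))
  b <- generate_cohort(cohort_config(n_patients = 60, seed = 5,
                                     missingness = NULL))
  expect_identical(a$data$blocks, b$data$blocks)
  expect_identical(a$outcomes, b$outcomes)
  c <- generate_cohort(cohort_config(n_patients = 60, seed = 6,
                                     missingness = NULL))
  expect_false(identical(a$data$blocks$rna, c$data$blocks$rna))
})

test_that("binary labels follow the horizon/censoring contract", {
  expect_identical(derive_binary_labels(200, 1, 365), 1L)
  expect_identical(derive_binary_labels(400, 0, 365), 0L)
  expect_identical(derive_binary_labels(200, 0, 365), NA_integer_)
  # event after horizon is a 0: the patient survived past it
  expect_identical(derive_binary_labels(400, 1, 365), 0L)
  expect_error(derive_binary_labels(-1, 1, 365), "positive")
  # exclusion count equals the number of patients censored before horizon
  co <- generate_cohort(cohort_config(n_patients = 250, seed = 7,
                                      missingness = NULL))
  oc <- co$outcomes
  expect_equal(sum(is.na(oc$label_1y_death)),
               sum(oc$os_time <= 365 & oc$os_event == 0))
  expect_equal(sum(is.na(oc$label_6m_progression)),
               sum(oc$pfs_time <= 183 & oc$pfs_event == 0))
})

test_that("exact-counts missingness reproduces every pattern frequency", {
  co <- generate_cohort(cohort_config(seed = 11))
  av <- co$data$availability
  pattern <- apply(av, 1, function(r)
    paste(colnames(av)[r], collapse = "+"))
  expect_equal(as.list(table(pattern))[names(default_pattern_counts())],
               as.list(as.integer(default_pattern_counts())),
               ignore_attr = TRUE)
  # deterministic given the seed
  co2 <- generate_cohort(cohort_config(seed = 11))
  expect_identical(co$data$availability, co2$data$availability)
})

test_that("missingness edge cases behave per contract", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 2,
                                      missingness = NULL))
  expect_true(all(co$data$availability))
  bad <- missingness_spec(pattern_counts = c(
    "clinical+radiomics+pathomics+rna" = 30L))
  expect_error(apply_missingness(co$data, bad, seed = 1), "sum")
  all_complete <- missingness_spec(
    pattern_counts = c("clinical+radiomics+pathomics+rna" = 40L),
    within_block_na_rate = 0)
  out <- apply_missingness(co$data, all_complete, seed = 1)
  expect_true(all(out$availability))
  expect_false(anyNA(out$blocks$pathomics))
})

test_that("unavailable blocks are fully NA and within-block NAs appear", {
  co <- generate_cohort(cohort_config(seed = 13))
  av <- co$data$availability
  for (k in colnames(av)) {
    blk <- co$data$blocks[[k]]
    expect_true(all(is.na(blk[!av[, k], ])))
  }
  # default within-block rate is positive: some available cells missing
  obs <- co$data$blocks$pathomics[av[, "pathomics"], ]
  expect_gt(sum(is.na(obs)), 0)
})

test_that("no prognostic signal yields chance-level concordance", {
  co <- generate_cohort(cohort_config(
    n_patients = 300, missingness = NULL,
    effect_sizes = c(clinical = 0, radiomics = 0, pathomics = 0, rna = 0),
    seed = 21))
  # score patients with an arbitrary feature: an honest predictor of noise
  c_idx <- uno_cindex(co$data$blocks$rna[, 1], co$outcomes$os_time,
                      co$outcomes$os_event)
  expect_lt(abs(c_idx - 0.5), 0.07)
})

test_that("a strong rna latent is recovered by its own oracle score", {
  co <- generate_cohort(cohort_config(
    n_patients = 300, missingness = NULL,
    effect_sizes = c(clinical = 0, radiomics = 0, pathomics = 0, rna = 1),
    seed = 22))
  c_idx <- uno_cindex(co$latents$rna[, 1], co$outcomes$os_time,
                      co$outcomes$os_event)
  expect_gt(c_idx, 0.7)
})

test_that("generated survival matches the closed-form exponential median", {
  h0 <- log(2) / 756
  co <- generate_cohort(cohort_config(
    n_patients = 10000, missingness = NULL,
    effect_sizes = c(clinical = 0, radiomics = 0, pathomics = 0, rna = 0),
    baseline_hazard_os = h0, censoring_window = 1e7, dropout_rate = 0,
    seed = 31))
  km <- km_estimate(co$outcomes$os_time, co$outcomes$os_event)
  km_median <- km$time[which(km$surv <= 0.5)[1]]
  expect_lt(abs(km_median - 756) / 756, 0.05)
})

test_that("invalid configs are rejected", {
  expect_error(cohort_config(baseline_hazard_os = -1), "positive")
  expect_error(cohort_config(n_patients = 0))
})

test_that("lesion cohorts honor the SUV threshold and reproducibility", {
  lc <- generate_lesion_cohort(30, seed = 4)
  expect_true(all(lc$lesions$suv_max >= 2.5))
  lc2 <- generate_lesion_cohort(30, seed = 4)
  expect_identical(lc, lc2)
  # zero intensity yields empty lesion lists
  empty <- generate_lesion_cohort(
    5, region_intensity = c(primary_ipsilateral_lung = 0), seed = 1)
  expect_equal(nrow(empty$lesions), 0L)
  expect_equal(nrow(empty$rois), 5L)
})

test_that("cohorts round-trip through delimited files", {
  co <- generate_cohort(cohort_config(
    n_patients = 30, seed = 17,
    missingness = missingness_spec(mode = "bernoulli",
                                   within_block_na_rate = 0.05)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$data$blocks$clinical, co$data$blocks$clinical,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(back$data$availability),
               unname(co$data$availability))
  expect_equal(back$outcomes$os_time, co$outcomes$os_time,
               tolerance = 1e-12)
})
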