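test_that("log-rank test matches a hand-computed two-group table", {
  # groups A/B, event times chosen so the O-E arithmetic is tractable
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  groups <- rep(c("A", "B"), each = 5)
  res <- logrank_test(groups, time, event)
  # independent oracle: accumulate O-E and hypergeometric variance per
  # distinct event time
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & groups == "A")
    n_t <- sum(at_risk); n_a <- sum(at_risk & groups == "A")
    o_minus_e <- o_minus_e + d_a - d * n_a / n_t
    if (n_t > 1)
      v <- v + d * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d) / (n_t - 1)
  }
  expect_equal(res$statistic, o_minus_e^2 / v, tolerance = 1e-9)
  # identical groups carry no signal
  same <- logrank_test(rep(c("A", "B"), each = 10), c(1:10, 1:10),
                       rep(1, 20))
  expect_lt(same$statistic, 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(rep("A", 5), 1:5, rep(1, 5)), "two")
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  time <- c(3, 1, 4, 2, 5)
  km <- km_estimate(time, rep(1, 5))
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_true(all(km$lower <= km$surv, na.rm = TRUE))
  expect_true(all(km$upper >= km$surv, na.rm = TRUE))
})

test_that("learned cutoffs maximize the training log-rank statistic", {
  d <- two_regime_cohort(seed = 111)
  th <- learn_threshold(d$score, d$time, d$event, task = "survival")
  # brute-force oracle over the same candidate grid
  best <- -Inf; best_ct <- NA
  for (ct in th$candidates) {
    hi <- d$score > ct
    if (!any(hi) || all(hi)) next
    if (sum(d$event[hi]) < 1 || sum(d$event[!hi]) < 1) next
    st <- logrank_test(hi, d$time, d$event)$statistic
    if (st > best) { best <- st; best_ct <- ct }
  }
  expect_equal(th$cutoff, best_ct)
  expect_equal(th$statistic, best)
  # the recovered cutoff sits near the true mixing quantile (50th)
  q_hat <- mean(d$score <= th$cutoff) * 100
  expect_lt(abs(q_hat - 50), 5)
  # constant predictions fall back to the median
  flat <- learn_threshold(rep(0.3, 100), d$time[1:100], d$event[1:100],
                          task = "survival")
  expect_true(flat$degenerate)
  expect_equal(flat$cutoff, 0.3)
})

test_that("the cutoff grid respects the configured percentile range", {
  d <- two_regime_cohort(seed = 112)
  th <- learn_threshold(d$score, d$time, d$event, task = "survival")
  expect_gte(th$cutoff, quantile(d$score, 0.30))
  expect_lte(th$cutoff, quantile(d$score, 0.70))
  # classifiers also scan the 0.5 probability threshold
  th_b <- learn_threshold(d$score, d$time, d$event, task = "binary")
  expect_true(0.5 %in% th_b$candidates)
})

test_that("membership aggregation is a majority vote with high-risk ties", {
  m <- cbind(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
  agg <- aggregate_membership(m)
  expect_equal(agg$frequency, c(1, 0, 0.5))
  expect_equal(agg$group, c("high", "low", "high"))
  # invariant to scheme ordering
  agg2 <- aggregate_membership(m[, 2:1])
  expect_identical(agg$group, agg2$group)
})

test_that("cross-validated risk groups separate a two-regime cohort", {
  d <- two_regime_cohort(n = 150, seed = 113)
  # pseudo out-of-fold predictions: the score itself across 5 schemes
  preds <- matrix(rep(d$score, 5), ncol = 5)
  schemes <- make_cv_schemes(d$event, n_repeats = 5, n_folds = 5, seed = 6)
  rg <- cv_risk_groups(preds, schemes, d$time, d$event)
  expect_true(all(rg$group %in% c("low", "high")))
  lr <- logrank_test(rg$group, d$time, d$event)
  expect_lt(lr$p, 0.01)
  # the learned grouping matches the generating regimes almost everywhere
  expect_gt(mean((rg$group == "high") == d$high), 0.9)
})

test_that("quartile stratification balances groups and tracks risk", {
  d <- two_regime_cohort(n = 100, seed = 114)
  qs <- quartile_stratify(d$score, d$time, d$event, horizon = 365)
  expect_equal(as.integer(table(qs$group)), rep(25L, 4))
  # monotone score-risk link shows up as higher top-quartile event rates
  expect_gt(qs$summary$rate[4], qs$summary$rate[1])
  # heavy ties still split into balanced quarters
  qs_tied <- quartile_stratify(rep(1, 100), d$time, d$event)
  expect_equal(as.integer(table(qs_tied$group)), rep(25L, 4))
})

test_that("multivariate Cox recovers a planted coefficient", {
  set.seed(115)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  t <- rexp(n, 0.002 * exp(0.8 * x1))
  cns <- runif(n, 200, 4000)
  time <- pmin(t, cns); event <- as.integer(t <= cns)
  cx <- fit_cox_multivariate(data.frame(x1 = x1, x2 = x2), time, event)
  co <- cx$coefficients
  # x1 is standardized with sd ~ 1, so the log HR per SD is ~ 0.8
  expect_lt(abs(co$log_hr[co$covariate == "x1"] - 0.8), 0.15)
  expect_true(co$lower[1] <= co$log_hr[1] & co$log_hr[1] <= co$upper[1])
  # a pure-noise covariate is near zero with a covering CI
  expect_lt(abs(co$log_hr[co$covariate == "x2"]), 0.15)
  # doubling a covariate's scale pre-standardization changes nothing
  cx2 <- fit_cox_multivariate(data.frame(x1 = 2 * x1, x2 = x2), time,
                              event)
  expect_equal(cx$coefficients$log_hr, cx2$coefficients$log_hr,
               tolerance = 1e-8)
})

test_that("missing scores are filled per task convention", {
  set.seed(116)
  n <- 120
  s <- runif(n); s[1:10] <- NA
  t <- rexp(n, 0.01); ev <- rep(1L, n)
  cx <- fit_cox_multivariate(data.frame(s = s), t, ev,
                             score_cols = "s",
                             score_task = c(s = "binary"))
  expect_equal(cx$n, n)   # nobody dropped: NAs filled with 0.5
})

test_that("likelihood-ratio tests compare nested Cox models", {
  set.seed(117)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  t <- rexp(n, 0.002 * exp(0.7 * x1))
  ev <- rep(1L, n)
  full <- fit_cox_multivariate(data.frame(x1 = x1, x2 = x2), t, ev)
  red <- fit_cox_multivariate(data.frame(x1 = x1), t, ev)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$statistic, 0)
  # dropping the informative covariate is decisively rejected
  red2 <- fit_cox_multivariate(data.frame(x2 = x2), t, ev)
  expect_lt(likelihood_ratio_test(full, red2)$p, 1e-6)
  expect_error(likelihood_ratio_test(red, full), "nested")
})
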