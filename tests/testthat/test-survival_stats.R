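test_that("Kaplan-Meier estimator handles degenerate and worked cases", {
  allc <- km_fit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(allc$survival == 1))
  single <- km_fit(5, 1)
  expect_equal(single$survival, 0)
  expect_equal(single$time, 5)
  # 6-subject worked set against the hand product-limit computation
  h <- km_hand_set
  km <- km_fit(h$time, h$event)
  expect_equal(km$survival[km$time %in% c(1, 3, 5, 7)], h$surv_at_events,
               tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_error(km_fit(c(0, 1), c(1, 1)), "positive")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(2)
  t <- sort(rexp(40, 0.1))
  km <- km_fit(t, rep(1, 40))
  expect_equal(km$survival, 1 - seq_len(40) / 40, tolerance = 1e-12)
})

test_that("log-rank test is symmetric, matches permutations, detects separation", {
  h <- km_hand_set
  # duplicated group: chi-square exactly 0
  lr0 <- logrank_test(rep(h$time, 2), rep(h$event, 2), rep(c("A", "B"), each = 6))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$df, 1L)
  # two-group p against a 10,000-permutation reference at n = 20
  co <- simulate_cohort(cohort_params(n_patients = 20, log_hr = log(3),
                                      baseline_hazard = 0.012, seed = 55))
  grp <- co$ki67_ck_ratio > 0.186
  lr <- logrank_test(co$dfs_months, co$event, grp)
  set.seed(99)
  chi_obs <- ki67ck:::logrank_chi2(co$dfs_months, co$event, grp)
  perm <- replicate(10000, ki67ck:::logrank_chi2(co$dfs_months, co$event,
                                                 sample(grp)))
  p_perm <- mean(perm >= chi_obs - 1e-12)
  # tolerance covers Monte-Carlo error plus the chi-square approximation
  expect_equal(lr$p, p_perm, tolerance = 0.04)
  # complete separation: all A events strictly before any B event
  sep <- logrank_test(1:10, rep(1, 10), rep(c("A", "B"), each = 5))
  expect_lt(sep$p, 0.01)
  expect_error(logrank_test(1:4, c(1, 1, 1, 1), rep("A", 4)), "two")
  # df = 1 identity: chi-square is the squared standardised O-E score
  expect_equal(lr$chi_square, chi_obs, tolerance = 1e-10)
})

test_that("Cox fit maximises the Breslow partial likelihood", {
  # 5-subject toy data against a grid-search maximiser
  time <- c(2, 4, 6, 8, 10); event <- c(1, 1, 0, 1, 1); x <- c(1, 0, 1, 0, 0)
  fit <- cox_fit(time, event, data.frame(x = x))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, numeric(1), time = time, event = event, x = x)
  expect_equal(fit$coef[1], grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$hr[1], exp(fit$coef[1]))
  expect_true(fit$ci_low[1] <= fit$hr[1] && fit$hr[1] <= fit$ci_high[1])
})

test_that("Cox null behaviour, symmetry and parameter recovery hold", {
  # permuted labels: small coefficient, CI covers 1
  set.seed(17)
  co <- simulate_cohort(cohort_params(n_patients = 200, log_hr = log(2.5),
                                      baseline_hazard = 0.006, seed = 18))
  xperm <- sample(as.integer(co$ki67_ck_ratio > 0.186))
  fit0 <- cox_fit(co$dfs_months, co$event, data.frame(x = xperm))
  expect_lt(abs(fit0$coef[1]), 0.6)
  expect_true(fit0$ci_low[1] <= 1 && 1 <= fit0$ci_high[1])
  # duplicated-and-relabeled data: coefficient exactly 0
  h <- km_hand_set
  dup <- cox_fit(rep(h$time, 2), rep(h$event, 2),
                 data.frame(g = rep(c(0, 1), each = 6)))
  expect_equal(dup$coef[1], 0, tolerance = 1e-8)
  # recovery: simulated HR = 2 estimated within [1.5, 2.7]
  co2 <- simulate_cohort(cohort_params(n_patients = 500, log_hr = log(2),
                                       baseline_hazard = 0.006,
                                       censor_rate = 0.001, seed = 77))
  fit2 <- cox_fit(co2$dfs_months, co2$event,
                  data.frame(grade_ii = as.integer(co2$ki67_ck_ratio > 0.186)))
  expect_gte(fit2$hr[1], 1.5)
  expect_lte(fit2$hr[1], 2.7)
  expect_error(cox_fit(co2$dfs_months, co2$event, data.frame(k = rep(1, 500))),
               "constant")
  # perfect separation is flagged, not silently returned
  w <- capture_warnings(cox_fit(1:10, rep(1, 10),
                                data.frame(x = rep(c(1, 0), each = 5))))
  expect_true(any(grepl("separation|unreliable|converged", w)))
})

test_that("AUC follows Mann-Whitney concordance with Hanley-McNeil intervals", {
  out <- c(rep(1, 6), rep(0, 10))
  perfect <- roc_auc(c(rep(2, 6), rep(1, 10)), out)
  expect_equal(perfect$auc, 1)
  flat <- roc_auc(rep(3, 16), out)
  expect_equal(flat$auc, 0.5)
  # binary predictor: AUC = (sensitivity + specificity) / 2, and both equal
  # the exhaustive pair-counting oracle
  set.seed(3)
  pred <- rbinom(60, 1, 0.4); o <- rbinom(60, 1, 0.35)
  r <- roc_auc(pred, o)
  sens <- mean(pred[o == 1] == 1); spec <- mean(pred[o == 0] == 0)
  expect_equal(r$auc, (sens + spec) / 2, tolerance = 1e-12)
  expect_equal(r$auc, pairwise_auc(pred, o), tolerance = 1e-12)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  # Hanley-McNeil standard error, evaluated directly
  n1 <- sum(o); n0 <- sum(1 - o); a <- r$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0))
  expect_equal(r$se, se, tolerance = 1e-12)
  # monotone transform invariance on a continuous predictor
  set.seed(6)
  cont <- rnorm(60) + o
  expect_equal(roc_auc(cont, o)$auc, roc_auc(exp(cont), o)$auc, tolerance = 1e-12)
  expect_error(roc_auc(cont, rep(1, 60)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  o <- rbinom(80, 1, 0.4)
  pred <- rnorm(80) + 0.8 * o
  r <- roc_auc(pred, o)
  ref <- as.numeric(pROC::auc(pROC::roc(o, pred, quiet = TRUE, direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("ROC outcome construction excludes early-censored records", {
  time <- c(10, 30, 70, 65, 59)
  event <- c(1, 0, 0, 1, 0)
  expect_message(ro <- roc_outcome(time, event, horizon = 60), "excluded 2")
  expect_equal(sum(ro$keep), 3)
  expect_equal(ro$outcome, c(1, 0, 0))
})
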