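test_that("concordance index matches the all-pairs oracle and survival::concordance", {
  # perfectly anti-ordered scores, all events
  t <- c(5, 3, 9, 1); th <- -t
  expect_equal(concordance_index(th, t, rep(1, 4)), 1)
  # all tied scores
  expect_equal(concordance_index(rep(2, 4), t, rep(1, 4)), 0.5)

  # worked 5-patient example against explicit enumeration
  th5 <- c(2, 1, 3, 0, 1); t5 <- c(1, 3, 2, 5, 4); e5 <- c(1, 1, 0, 1, 1)
  expect_equal(concordance_index(th5, t5, e5), bf_cindex(th5, t5, e5))

  set.seed(21)
  for (r in 1:25) {
    n <- sample(3:100, 1)
    th <- rnorm(n)
    t <- sample(1:25, n, TRUE)
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    expect_equal(concordance_index(th, t, e), bf_cindex(th, t, e))
  }

  # independent cross-check on untied continuous data
  n <- 80; th <- rnorm(n); t <- rexp(n); e <- rbinom(n, 1, 0.7); e[1] <- 1
  ref <- survival::concordance(survival::Surv(t, e) ~ th, reverse = TRUE)
  expect_equal(concordance_index(th, t, e), unname(ref$concordance))

  expect_error(concordance_index(c(1, 2), c(3, 3), c(1, 1)), "comparable")
})

test_that("Kaplan-Meier estimate equals the hand product-limit and its invariances", {
  # 4 distinct event times step through quarters
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km$surv) <= 0))

  # no events: flat at 1
  km0 <- km_estimate(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # censoring handled as the oracle dictates
  set.seed(22)
  t <- sample(1:10, 30, TRUE); e <- rbinom(30, 1, 0.6)
  km1 <- km_estimate(t, e)
  or <- bf_km(t, e)
  expect_equal(km1$surv[match(or$time, km1$time)], or$surv)

  # duplicating every record leaves the curve unchanged
  km2 <- km_estimate(rep(t, 2), rep(e, 2))
  expect_equal(km2$surv, km1$surv)

  # with no censoring the curve is the empirical survival function
  tt <- c(3, 1, 4, 1, 5)
  kme <- km_estimate(tt, rep(1, 5))
  expect_equal(kme$surv, sapply(kme$time, function(x) mean(tt > x)))
})

test_that("log-rank test is calibrated under permutation and detects separation", {
  set.seed(23)
  t <- rexp(60); e <- rbinom(60, 1, 0.7); e[1] <- 1
  g <- rep(0:1, 30)
  ps <- replicate(200, logrank_test(t, e, sample(g))$p)
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)
  expect_true(all(replicate(20, logrank_test(t, e, sample(g))$chi2) >= 0))

  # strong separation: hazard ratio 3
  hits <- replicate(40, {
    g2 <- rep(0:1, each = 100)
    t2 <- rexp(200, ifelse(g2 == 1, 3, 1) * 0.5)
    c2 <- rexp(200, 0.2)
    ev <- as.integer(t2 <= c2)
    logrank_test(pmin(t2, c2), ev, g2)$p < 0.01
  })
  expect_gte(mean(hits), 0.95)

  expect_error(logrank_test(t, e, rep(1, 60)), "non-empty")
})

test_that("median stratification uses a strict > cut", {
  g <- median_stratify(c(1, 2, 3, 4))
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_identical(as.character(median_stratify(rep(5, 6))), rep("low", 6))
  expect_identical(sort(as.character(median_stratify(c(2, 9)))),
                   c("high", "low"))
})

test_that("clinical Cox baseline recovers simulated effects and rejects degenerate input", {
  set.seed(24)
  x <- rbinom(1000, 1, 0.5)
  # null: true HR 1
  t0 <- rexp(1000, 0.01)
  c0 <- rexp(1000, 0.004)
  f0 <- coxph_baseline(cbind(x = x), pmin(t0, c0), as.integer(t0 <= c0))
  expect_lt(abs(unname(f0$coefficients)), 0.1)

  # true HR 2
  t2 <- rexp(1000, 0.01 * exp(log(2) * x))
  c2 <- rexp(1000, 0.004)
  f2 <- coxph_baseline(cbind(x = x), pmin(t2, c2), as.integer(t2 <= c2))
  expect_lt(abs(unname(f2$coefficients) - log(2)), 0.15)
  expect_length(f2$theta, 1000L)

  expect_error(coxph_baseline(cbind(z = rep(0, 10)), rexp(10), rep(1, 10)),
               "rank")
})

test_that("horizon AUC equals the Mann-Whitney count and ignores monotone rescaling", {
  expect_equal(as.numeric(horizon_auc(rep(1, 10), 1:10, rep(1, 10), 5)), 0.5)

  th <- c(5, 4, 3, 2, 1, 0)
  t <- c(100, 200, 400, 900, 1000, 1200)
  e <- c(1, 1, 1, 0, 0, 0)
  # cases: first three; controls: last three (horizon between)
  expect_equal(as.numeric(horizon_auc(th, t, e, 500)), 1)

  # hand-assigned mixed outcomes vs explicit pair counting
  th6 <- c(2, 0, 1, 3, 1, 1)
  t6 <- c(100, 300, 2000, 2000, 50, 2000)
  e6 <- c(1, 1, 0, 0, 0, 0)
  cases <- th6[c(1, 2)]; controls <- th6[c(3, 4, 6)]
  mw <- (sum(outer(cases, controls, ">")) +
           0.5 * sum(outer(cases, controls, "=="))) / (2 * 3)
  a <- horizon_auc(th6, t6, e6, 1825)
  expect_equal(as.numeric(a), mw)
  expect_equal(attr(a, "n_excluded"), 1L)   # censored at day 50

  expect_equal(as.numeric(horizon_auc(exp(th6), t6, e6, 1825)), mw)
  expect_error(horizon_auc(th, t, rep(0, 6), 50), "case")
})

test_that("cross-validation harness partitions patients and is reproducible", {
  cohort <- make_cohort(n = 40, build_graphs = FALSE, seed = 41)
  spec <- list(
    fit = function(ch, ids, seed) {
      sb <- ch$survival[match(ids, ch$survival$patient_id), ]
      coxph_baseline(sb[, c("age", "stage")], sb$time, sb$event)
    },
    predict = function(fit, ch, ids) {
      sb <- ch$survival[match(ids, ch$survival$patient_id), ]
      setNames(as.vector(as.matrix(sb[, c("age", "stage")]) %*%
                           fit$coefficients), ids)
    })
  r1 <- cv_harness(cohort, spec, folds = 5, seed = 3)
  expect_identical(sort(r1$pooled$patient_id), sort(cohort$survival$patient_id))
  expect_identical(anyDuplicated(r1$pooled$patient_id), 0L)
  expect_length(r1$per_fold, 5L)
  r2 <- cv_harness(cohort, spec, folds = 5, seed = 3)
  expect_identical(r1$assignment, r2$assignment)
  expect_equal(r1$pooled_c, r2$pooled_c)
})

test_that("a model trained on a null cohort scores near chance in cross-validation", {
  cohort <- make_cohort(n = 120, beta = 0, build_graphs = FALSE, seed = 42)
  ocfg <- omics_config(hidden = list(expression = c(16, 8), mutation = c(16, 8),
                                     methylation = c(16, 8)), shared_dim = 4)
  spec <- list(
    fit = function(ch, ids, seed)
      fit_omics_branch(ch, ocfg,
                       train_config(epochs = 15, lr0 = 0.05, init_sd = 0.1,
                                    seed = seed), ids = ids),
    predict = function(fit, ch, ids) predict_risk(fit, ch, ids))
  res <- cv_harness(cohort, spec, folds = 10, seed = 5)
  expect_gt(res$mean_c, 0.45)
  expect_lt(res$mean_c, 0.55)
})
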