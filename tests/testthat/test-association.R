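test_that("logistic association reports per-SD log odds with Wald CI", {
  set.seed(101)
  z <- standardize(rnorm(4000))
  y <- simulate_case_control(z, risk_beta = 0, baseline_prevalence = 0.5,
                             seed = 102)
  res <- logistic_assoc(z, y)
  expect_equal(res$status, "ok")
  expect_lt(abs(res$effect), 0.15)
  expect_true(res$ci_low <= res$effect && res$effect <= res$ci_high)

  expect_error(logistic_assoc(z, rep(1, 4000)), "no variation")

  # gate: strata at or below the case threshold are skipped, not errors
  small <- logistic_assoc(z[1:150], rbinom(150, 1, 0.3), min_cases = 100)
  expect_equal(small$status, "skipped")
  expect_true(is.na(small$effect))

  # complete separation is flagged with no coefficient
  xs <- c(rnorm(50, -3), rnorm(50, 3))
  ys <- rep(c(0, 1), each = 50)
  sep <- logistic_assoc(standardize(xs), ys, min_cases = 10)
  expect_equal(sep$status, "separation")
  expect_true(is.na(sep$effect))
})

test_that("linear association matches closed-form least squares", {
  x <- 1:5
  res <- linear_assoc(c(1, 3, 2, 5, 4), x)
  expect_equal(res$effect, 0.8)

  exact <- suppressWarnings(linear_assoc(2 * (1:10), 1:10))
  expect_equal(exact$effect, 2)
  expect_equal(exact$stderr, 0)

  set.seed(103)
  null_fit <- linear_assoc(rnorm(500), rnorm(500))
  expect_lt(abs(null_fit$effect), 0.2)

  expect_error(linear_assoc(rnorm(5), rep(1, 5)), "zero-variance")
  expect_error(linear_assoc(1:2, 1:2), "more than 2")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  set.seed(104)
  p <- runif(40)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # discoveries non-increasing as the level drops
  for (q in c(0.2, 0.1, 0.05, 0.01))
    expect_gte(sum(adj < 0.2), sum(adj < q))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DerSimonian-Laird pooling matches hand and metafor results", {
  hom <- meta_random_effects(rep(0.5, 3), rep(0.1, 3))
  expect_equal(hom$pooled_effect, 0.5)
  expect_equal(hom$Q, 0)
  expect_equal(hom$tau2, 0)

  hand <- meta_random_effects(c(1, 3), c(1, 1))
  expect_equal(hand$Q, 2)
  expect_equal(hand$tau2, 1)
  expect_equal(hand$pooled_effect, 2)
  expect_equal(hand$pooled_se, 1)

  expect_error(meta_random_effects(1, 1), "at least 2")

  set.seed(105)
  for (i in 1:5) {
    k <- sample(3:8, 1)
    eff <- rnorm(k)
    se <- runif(k, 0.1, 0.5)
    mine <- meta_random_effects(eff, se)
    expect_true(mine$tau2 >= 0)
    expect_gte(mine$pooled_effect, min(eff))
    expect_lte(mine$pooled_effect, max(eff))
    rma <- metafor::rma(yi = eff, sei = se, method = "DL")
    expect_equal(mine$pooled_effect, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(mine$pooled_se, rma$se, tolerance = 1e-8)
    expect_equal(mine$tau2, rma$tau2, tolerance = 1e-8)
    expect_equal(mine$Q, rma$QE, tolerance = 1e-8)
  }

  # tau2 = 0 reduces to inverse-variance fixed-effect pooling
  eff <- c(0.2, 0.25, 0.22)
  se <- c(0.3, 0.4, 0.5)
  m <- meta_random_effects(eff, se)
  expect_equal(m$tau2, 0)
  w <- 1 / se^2
  expect_equal(m$pooled_effect, sum(w * eff) / sum(w))
})

test_that("AUC equals the Mann-Whitney probability with half ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(106)
  s <- rnorm(200)
  y <- rbinom(200, 1, plogis(s))
  a <- roc_auc(s, y)
  expect_equal(roc_auc(exp(s), y), a)          # monotone invariance
  expect_equal(roc_auc(rank(s), y), a)
  expect_equal(a, as.numeric(pROC::auc(y, s, quiet = TRUE)))
})

test_that("Cox fit matches a grid-search partial likelihood oracle", {
  time <- c(2, 5, 7, 11)
  event <- c(1, 1, 1, 1)
  x <- c(1.2, -0.5, 0.3, -1.0)
  fit <- cox_fit(time, event, x)
  expect_equal(fit$hazard_coef, oracle_cox_coef(time, event, x),
               tolerance = 2e-3)

  set.seed(107)
  t2 <- rexp(30)
  e2 <- rbinom(30, 1, 0.8)
  x2 <- rnorm(30)
  fit2 <- cox_fit(t2, e2, x2)
  expect_equal(fit2$hazard_coef, oracle_cox_coef(t2, e2, x2),
               tolerance = 2e-3)

  expect_error(cox_fit(t2, rep(0, 30), x2), "at least 2 events")
  expect_error(cox_fit(t2, e2, rep(1, 30)), "constant covariate")
})

test_that("Cox recovery: mean estimate near the true hazard coefficient", {
  est <- vapply(1:50, function(i) {
    z <- standardize(rnorm(500))
    surv <- simulate_survival(z, hazard_beta = 0.7, censoring_rate = 0.2,
                              seed = 200 + i)
    cox_fit(surv$time, surv$event, z)$hazard_coef
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.2)

  # null covariate: small coefficient
  set.seed(108)
  z <- standardize(rnorm(800))
  surv <- simulate_survival(z, hazard_beta = 0, censoring_rate = 0.2,
                            seed = 109)
  expect_lt(abs(cox_fit(surv$time, surv$event, z)$hazard_coef), 0.15)
})

test_that("maxstat cutpoint maximizes the brute-force log-rank statistic", {
  set.seed(110)
  # bimodal covariate with strongly different survival across modes
  grp <- rep(c(0, 1), each = 60)
  x <- c(rnorm(60, -2, 0.3), rnorm(60, 2, 0.3))
  surv <- simulate_survival(ifelse(grp == 1, 1.5, -1.5), hazard_beta = 1,
                            censoring_rate = 0.1, seed = 111)
  fit <- maxstat_cutpoint(surv$time, surv$event, x)
  expect_gt(fit$cutpoint, -1.5)
  expect_lt(fit$cutpoint, 1.5)
  expect_lt(fit$p_dichotomized, 1e-4)

  # the selected statistic equals the max over the candidate grid,
  # recomputed from first principles
  stats_bf <- vapply(fit$candidates, function(cc)
    abs(oracle_logrank(surv$time, surv$event, x <= cc)), numeric(1))
  expect_equal(fit$statistic, max(stats_bf), tolerance = 1e-8)
  expect_equal(fit$cutpoint, fit$candidates[which.max(stats_bf)])

  expect_error(maxstat_cutpoint(surv$time, surv$event, rep(1, 120)),
               "fewer than 2")

  # combined fit reports both p-values
  sf <- survival_fit(surv$time, surv$event, standardize(x))
  expect_true(all(c("p_continuous", "p_dichotomized", "cutpoint") %in%
                    names(sf)))
  expect_true(sf$cutpoint > min(x) && sf$cutpoint < max(x))
})
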