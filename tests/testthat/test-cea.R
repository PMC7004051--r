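test_that("QALY area under the curve follows the trapezoid rule", {
  t3 <- c(0, 0.5, 1)
  expect_equal(qaly_auc(c(1, 1, 1), t3), 1.0)
  expect_equal(qaly_auc(c(0, 1, 0), t3), 0.5)
  # utility means at 0/6/12 months
  expect_equal(qaly_auc(c(0.502, 0.542, 0.555), t3), 0.53525)
  # matrix input, unequal spacing
  expect_equal(qaly_auc(rbind(c(0, 2), c(1, 1)), c(0, 2)), c(2, 2))
  expect_error(qaly_auc(c(0.5, NA, 0.7), t3), "complete")
})

test_that("incremental estimates are arm mean differences with SUR covariance", {
  set.seed(5)
  arm <- rep(c("c", "t"), each = 40)
  e <- rnorm(80, 0.5, 0.2)
  cost <- rnorm(80, 1000, 300)
  inc <- estimate_incrementals(e, cost, arm, comparator = "c")
  expect_equal(inc$delta_e, mean(e[41:80]) - mean(e[1:40]))
  expect_equal(inc$delta_c, mean(cost[41:80]) - mean(cost[1:40]))
  # identical outcomes across arms: exact null
  inc0 <- estimate_incrementals(rep(e[1:40], 2), rep(cost[1:40], 2), arm,
                                comparator = "c")
  expect_equal(inc0$delta_e, 0)
  expect_equal(inc0$delta_c, 0)
  expect_error(estimate_incrementals(e, cost, rep("c", 80), "c"),
               "two arms")
})

test_that("SUR covariance matches a brute-force resimulation oracle", {
  # true joint distribution of (effect, cost): correlated bivariate normal;
  # compare the analytic covariance of (delta_e, delta_c) with the empirical
  # covariance of estimates over independent resimulated datasets
  set.seed(77)
  n <- 60
  S <- matrix(c(0.04, 2, 2, 400^2 / 4), 2)
  nrep <- 2000
  ests <- matrix(0, nrep, 2)
  Vs <- matrix(0, 2, 2)
  for (r in seq_len(nrep)) {
    Y0 <- MASS::mvrnorm(n, c(0.5, 900), S)
    Y1 <- MASS::mvrnorm(n, c(0.6, 1000), S)
    inc <- estimate_incrementals(c(Y0[, 1], Y1[, 1]), c(Y0[, 2], Y1[, 2]),
                                 rep(c("c", "t"), each = n), "c")
    ests[r, ] <- c(inc$delta_e, inc$delta_c)
    Vs <- Vs + inc$cov / nrep
  }
  emp <- cov(ests)
  # elementwise agreement within simulation error (~ sqrt(2/nrep) relative)
  expect_lt(abs(Vs[1, 1] / emp[1, 1] - 1), 0.15)
  expect_lt(abs(Vs[2, 2] / emp[2, 2] - 1), 0.15)
  expect_lt(abs(Vs[1, 2] / emp[1, 2] - 1), 0.25)
})

test_that("Rubin's rules reproduce hand-computed pooling", {
  p <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$W, 1)
  expect_equal(p$B, 1)
  expect_equal(p$T, 7 / 3)
  expect_equal(p$df, 2 * (1 + 3 / 4)^2)   # 6.125
  # B = 0 limit: total variance is the within variance, normal interval
  p0 <- rubin_pool(c(2, 2, 2), c(4, 4, 4))
  expect_equal(p0$T, 4)
  expect_equal(p0$df, Inf)
  expect_equal(p0$ci, 2 + c(-1, 1) * qnorm(0.975) * 2)
  # scale equivariance of the within component
  p2 <- rubin_pool(c(1, 2, 3), c(2, 2, 2))
  expect_equal(p2$W, 2 * p$W)
  expect_equal(p2$T - (1 + 1 / 3) * p2$B, 2 * (p$T - (1 + 1 / 3) * p$B))
  expect_error(rubin_pool(1, 1), "m >= 2")
  # multivariate pooling: covariance is W + (1 + 1/m) B
  Qs <- list(c(1, 10), c(2, 20), c(3, 30))
  Us <- list(diag(2), diag(2), diag(2))
  pm <- rubin_pool(Qs, Us)
  expect_equal(pm$estimate, c(2, 20))
  expect_equal(pm$T, diag(2) + (1 + 1 / 3) * cov(do.call(rbind, Qs)))
})

test_that("ICER is the cost/effect ratio with guarded edge cases", {
  expect_equal(icer(1000, 0.1), 10000)
  expect_equal(round(icer(996, 0.088)), 11318)
  expect_warning(out <- icer(500, 0), "undefined")
  expect_true(is.na(out))
  expect_warning(icer(-500, 0.1), "quadrant")
})

test_that("CEAC follows the normal approximation of net benefit", {
  V <- matrix(c(0.0025, 0, 0, 10000), 2)
  cv <- ceac(0.1, 1000, V, lambda = 20000)
  expect_equal(cv$inb, 1000)
  expect_equal(cv$se_inb, sqrt(20000^2 * 0.0025 + 10000), tolerance = 1e-12)
  expect_equal(cv$prob_ce, pnorm(1000 / sqrt(1.01e6)))
  expect_equal(round(cv$prob_ce, 3), 0.840)
  # lambda = 0: probability that costs fall
  c0 <- ceac(0.1, 1000, V, lambda = 0)
  expect_equal(c0$prob_ce, pnorm(-1000 / 100))
  # lambda -> infinity: probability of positive effect
  cinf <- ceac(0.1, 1000, V, lambda = 1e9)
  expect_equal(cinf$prob_ce, pnorm(0.1 / 0.05), tolerance = 1e-4)
  # monotone and continuous in lambda for a positive effect
  grid <- ceac(0.1, 1000, V)
  expect_true(all(diff(grid$prob_ce) >= 0))
  expect_lt(max(abs(diff(grid$prob_ce))), 0.2)
  expect_error(ceac(0.1, 1000, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("complete data give identical results across scenarios", {
  cfg <- mcar_config(n = 40)
  cfg$dropout$intercepts <- c(-50, -50)
  cfg$cost_missing$complete <- 0
  tr <- generate_trial(cfg, seed = 2)$observed
  suite <- run_sensitivity_suite(tr, scenarios = c("MAR", "J2R", "BMCF"),
                                 settings = test_settings(m = 5), seed = 3)
  s <- suite$summary
  for (col in c("delta_qaly", "delta_cost", "icer", "prob_ce")) {
    expect_equal(s[[col]][2], s[[col]][1])
    expect_equal(s[[col]][3], s[[col]][1])
  }
})

test_that("unknown scenario names are rejected before any fitting", {
  cfg <- mcar_config(n = 20)
  tr <- generate_trial(cfg, seed = 2)$observed
  expect_error(run_sensitivity_suite(tr, scenarios = c("MAR", "J3R"),
                                     settings = test_settings(m = 2)),
               "J3R")
})

test_that("MAR-pooled estimates are consistent on MCAR data as n grows", {
  true_de <- qaly_auc(c(0.5, 0.65, 0.7), c(0, .5, 1)) -
    qaly_auc(c(0.5, 0.55, 0.6), c(0, .5, 1))
  bias <- vapply(c(100, 300, 900), function(n) {
    cfg <- mcar_config(n = n)
    tr <- generate_trial(cfg, seed = 100 + n)$observed
    draws <- fit_all_arms(tr, test_settings(m = 8, burnin = 60), seed = 1)
    imps <- impute(tr, endpoint_assumptions("MAR", "MAR"), draws, seed = 2)
    res <- analyse_imputations(imps)
    abs(res$delta_qaly$estimate - true_de)
  }, 1)
  # absolute bias at the largest n is small relative to the smallest n's
  # sampling noise, and within ~3 SEs of zero at n = 900
  se900 <- sqrt(2 * (0.3^2 + 0.3^2) / 900)   # rough scale of delta-QALY SE
  expect_lt(bias[3], 3 * se900)
})
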