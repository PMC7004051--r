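# A two-visit effectiveness-only schema and a participant observed at the
# first visit, missing at the second, used for the mean-rule examples.
two_visit_case <- function() {
  schema <- simple_schema(Je = 2, cost = FALSE)
  tr <- pattern_trial("om", schema)
  list(schema = schema, profile = classify_missingness(tr))
}

test_that("assumption combinations validate", {
  expect_equal(endpoint_assumptions("j2r", "mar")$effectiveness, "J2R")
  expect_error(endpoint_assumptions("J2R", "LMCF"), "not supported")
  expect_error(endpoint_assumptions("XYZ"), "unknown assumption")
  expect_error(scenario_assumptions <- refcea:::scenario_assumptions("nope"),
               "valid scenarios")
})

test_that("mean rules follow each assumption's formula", {
  cs <- two_visit_case()
  mu_rand <- c(q1 = 1, q2 = 2)
  expect_equal(build_mean("MAR", mu_rand, NULL, cs$profile, 1, cs$schema),
               mu_rand)
  expect_equal(
    unname(build_mean("J2R", mu_rand, c(0, 0.5), cs$profile, 1, cs$schema)),
    c(1, 0.5))
  expect_equal(
    unname(build_mean("CIR", mu_rand, c(0.5, 0.7), cs$profile, 1,
                      cs$schema)),
    c(1, 1 + (0.7 - 0.5)))
  expect_equal(
    unname(build_mean("LMCF", mu_rand, NULL, cs$profile, 1, cs$schema)),
    c(1, 1))
  expect_equal(
    unname(build_mean("BMCF", mu_rand, NULL, cs$profile, 1, cs$schema)),
    c(1, 1))
  expect_error(build_mean("J2R", mu_rand, NULL, cs$profile, 1, cs$schema),
               "reference")
})

test_that("interim-missing values switch distribution only under the dropout policy", {
  schema <- simple_schema(Je = 3, cost = FALSE)
  tr <- pattern_trial("omo", schema)     # interim miss at visit 2
  profile <- classify_missingness(tr)
  mu_rand <- c(q1 = 1, q2 = 2, q3 = 3)
  mu_ref <- c(q1 = 0, q2 = 0.5, q3 = 0.9)
  # policy MAR: nothing is MNAR, the mean stays at the randomised arm's
  expect_equal(build_mean("J2R", mu_rand, mu_ref, profile, 1, schema,
                          interim = "mar"), mu_rand)
  # policy dropout: the interim value jumps to reference (J2R) or is carried
  # from the last pre-gap observation (LMCF), anchored before the gap
  expect_equal(
    unname(build_mean("J2R", mu_rand, mu_ref, profile, 1, schema,
                      interim = "dropout")), c(1, 0.5, 3))
  expect_equal(
    unname(build_mean("LMCF", mu_rand, mu_ref, profile, 1, schema,
                      interim = "dropout")), c(1, 1, 3))
  expect_equal(
    unname(build_mean("CIR", mu_rand, mu_ref, profile, 1, schema,
                      interim = "dropout")), c(1, 1 + 0.5 - 0, 3))
})

test_that("J2R/CIR covariance composition matches the block formulas", {
  # 2x2 worked case: B = 0.5, Qrow = [0.5, 1.75]
  Sr <- diag(2)
  Sf <- matrix(c(2, 1, 1, 2), 2)
  out <- build_covariance_j2r_cir(Sr, Sf, P = 1, Q = 2)
  expect_equal(out, matrix(c(1, 0.5, 0.5, 1.75), 2))
  # reduction identity and boundary cases
  expect_equal(build_covariance_j2r_cir(Sf, Sf, P = 1, Q = 2), Sf)
  expect_equal(build_covariance_j2r_cir(Sr, Sf, P = integer(), Q = 1:2), Sf)
  expect_equal(build_covariance_j2r_cir(Sr, Sf, P = 1:2, Q = integer()), Sr)
  expect_error(build_covariance_j2r_cir(Sr, Sf, P = 1, Q = 1), "partition")
})

test_that("composed covariance is symmetric PD for random PD inputs", {
  set.seed(42)
  for (rep in 1:40) {
    d <- sample(2:6, 1)
    Sr <- random_pd(d)
    Sf <- random_pd(d)
    Q <- sort(sample(d, sample(d - 1, 1)))
    P <- setdiff(seq_len(d), Q)
    out <- build_covariance_j2r_cir(Sr, Sf, P, Q)
    expect_equal(out, t(out))
    ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(ev))
    # marginal of the conditioning block always comes from the randomised arm
    expect_equal(out[P, P], Sr[P, P])
  }
})

test_that("the pattern joint reduces to the randomised draw when nothing is MNAR", {
  schema <- simple_schema(Je = 3)
  tr <- pattern_trial(c("oomm", "omom", "oooo"), schema)
  profile <- classify_missingness(tr)
  d <- 4
  set.seed(7)
  draw_rand <- list(mu = rnorm(d), Sigma = random_pd(d))
  draw_ref <- list(mu = rnorm(d), Sigma = random_pd(d))
  # MAR on both endpoints: exact equality
  j <- build_joint(endpoint_assumptions("MAR", "MAR"), draw_rand, draw_ref,
                   profile, 1, schema)
  expect_equal(j$mean, draw_rand$mu)
  expect_equal(j$cov, draw_rand$Sigma)
  expect_equal(j$mnar_missing, integer(0))
  # reference = randomised arm: the reference-anchored assumptions collapse
  # to MAR exactly
  for (a in c("J2R", "CIR")) {
    jj <- build_joint(endpoint_assumptions(a, a), draw_rand, draw_rand,
                      profile, 1, schema)
    expect_equal(jj$mean, draw_rand$mu, tolerance = 1e-10)
    expect_equal(jj$cov, draw_rand$Sigma, tolerance = 1e-10)
  }
  # LMCF/BMCF never read the reference draw: changing it changes nothing,
  # and the covariance stays the randomised arm's
  for (a in c("LMCF", "BMCF")) {
    asm <- endpoint_assumptions(a, "MAR")
    j1 <- build_joint(asm, draw_rand, draw_ref, profile, 1, schema)
    j2 <- build_joint(asm, draw_rand, draw_rand, profile, 1, schema)
    j3 <- build_joint(asm, draw_rand, NULL, profile, 1, schema)
    expect_equal(j1, j2)
    expect_equal(j1, j3)
    expect_equal(j1$cov, draw_rand$Sigma)
  }
  # a completer's joint is the randomised draw under any assumption
  jj <- build_joint(endpoint_assumptions("J2R", "J2R"), draw_rand, draw_ref,
                    profile, 3, schema)
  expect_equal(jj$mean, draw_rand$mu)
  expect_equal(jj$cov, draw_rand$Sigma)
})

test_that("assumptions never alter observed or covariate components", {
  schema <- trial_schema(covariates = "x",
                        eff_vars = c("q1", "q2", "q3"),
                        eff_times = c(0, .5, 1),
                        cost_vars = "cost", cost_times = 1,
                        arm_var = "arm", reference = "control")
  Y <- rbind(c(1, 0.4, 0.5, NA, NA), c(1, 0.4, 0.5, 0.6, 100))
  colnames(Y) <- schema_vars <- c("x", "q1", "q2", "q3", "cost")
  tr <- make_trial(Y, arm = c("active", "control"), schema)
  profile <- classify_missingness(tr)
  set.seed(11)
  draw_rand <- list(mu = rnorm(5), Sigma = random_pd(5))
  draw_ref <- list(mu = rnorm(5), Sigma = random_pd(5))
  ref <- build_joint(endpoint_assumptions("MAR", "MAR"), draw_rand, draw_ref,
                     profile, 1, schema)
  P <- ref$observed                    # covariate + observed components
  for (a in c("J2R", "CIR", "LMCF", "BMCF")) {
    asm <- endpoint_assumptions(a, if (a %in% c("J2R", "CIR")) a else "MAR")
    jj <- build_joint(asm, draw_rand, draw_ref, profile, 1, schema)
    expect_equal(jj$mean[P], ref$mean[P])
    expect_equal(jj$cov[P, P], ref$cov[P, P])
  }
})

test_that("differential endpoint assumptions split MAR and MNAR blocks", {
  schema <- simple_schema(Je = 3)
  # the classic mixed pattern: interim QoL miss + missing cost
  tr <- pattern_trial("omom", schema)
  profile <- classify_missingness(tr)
  set.seed(3)
  draw_rand <- list(mu = rnorm(4), Sigma = random_pd(4))
  draw_ref <- list(mu = rnorm(4), Sigma = random_pd(4))
  # J2R both endpoints, interim MAR: q2 is MAR-missing, cost MNAR
  j <- build_joint(endpoint_assumptions("J2R", "J2R", interim = "mar"),
                   draw_rand, draw_ref, profile, 1, schema)
  expect_equal(unname(j$mar_missing), 2L)   # q2
  expect_equal(unname(j$mnar_missing), 4L)  # cost
  # J2R effectiveness + MAR costs: nothing MNAR in this pattern, so the
  # joint equals the randomised draw (cost parameters untouched)
  j2 <- build_joint(endpoint_assumptions("J2R", "MAR"), draw_rand, draw_ref,
                    profile, 1, schema)
  expect_equal(j2$cov, draw_rand$Sigma)
  expect_equal(j2$mean, draw_rand$mu)
  # BMCF on a single-variable cost endpoint falls back to MAR for costs
  j3 <- build_joint(endpoint_assumptions("BMCF", "BMCF"), draw_rand,
                    draw_ref, profile, 1, schema)
  expect_equal(j3$mnar_missing, integer(0))
})

test_that("J2R marginal mean of an MNAR variable matches the mean rule", {
  # sampling oracle: draw the conditioning block from the randomised
  # marginal, the MNAR block from the reference conditional; the empirical
  # mean of the MNAR variable for a participant observed at the arm mean
  # must match build_mean's entry
  schema <- simple_schema(Je = 2, cost = FALSE)
  tr <- pattern_trial("om", schema)
  profile <- classify_missingness(tr)
  set.seed(21)
  draw_rand <- list(mu = c(1, 2), Sigma = random_pd(2))
  draw_ref <- list(mu = c(0, 0.5), Sigma = random_pd(2))
  j <- build_joint(endpoint_assumptions("J2R", "MAR"), draw_rand, draw_ref,
                   profile, 1, schema)
  nsim <- 2e4
  y1 <- draw_rand$mu[1] + sqrt(draw_rand$Sigma[1, 1]) * rnorm(nsim)
  B <- draw_ref$Sigma[2, 1] / draw_ref$Sigma[1, 1]
  s2 <- draw_ref$Sigma[2, 2] - B^2 * draw_ref$Sigma[1, 1]
  y2 <- draw_ref$mu[2] + B * (y1 - draw_rand$mu[1]) + sqrt(s2) * rnorm(nsim)
  # oracle joint moments vs composed parameters
  expect_lt(abs(mean(y2) - j$mean[2]), 3 * sd(y2) / sqrt(nsim))
  emp_cov <- cov(cbind(y1, y2))
  expect_lt(max(abs(emp_cov - j$cov)), 4 * max(j$cov) / sqrt(nsim) * 3)
})
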