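# Shared fixtures built in code: small schemas, hand-set trials, and a
# moderate synthetic config with known truth.

# schema without covariates: Je effectiveness points (+ optional single cost)
simple_schema <- function(Je = 3, cost = TRUE, reference = "control") {
  trial_schema(
    eff_vars = paste0("q", seq_len(Je)),
    eff_times = seq(0, 1, length.out = Je),
    cost_vars = if (cost) "cost" else character(),
    cost_times = if (cost) 1 else numeric(),
    arm_var = "arm", reference = reference)
}

# trial from an explicit matrix (NA = missing); default two balanced arms
make_trial <- function(Y, arm = NULL, schema) {
  if (is.null(arm))
    arm <- rep(c("control", "active"), length.out = nrow(Y))
  trial_data(Y, arm, schema)
}

# one participant per requested signature ("o"/"m" over the outcome columns),
# values filled with a deterministic ramp; both arms get a complete row so
# the trial validates
pattern_trial <- function(signatures, schema, arm = "active") {
  vars <- c(schema$eff_vars, schema$cost_vars)
  stopifnot(all(nchar(signatures) == length(vars)))
  base <- seq(0.4, 0.8, length.out = length(vars))
  rows <- lapply(signatures, function(s) {
    v <- base
    v[strsplit(s, "")[[1]] == "m"] <- NA
    v
  })
  Y <- do.call(rbind, c(rows, list(base, base)))
  colnames(Y) <- vars
  make_trial(Y, arm = c(rep(arm, length(signatures)), "control", "active"),
             schema)
}

# a random PD covariance of dimension d (correlation-like scale)
random_pd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  S <- crossprod(A) / d + diag(0.2, d)
  scale * S
}

# fixed posterior "draws" object holding the same (mu, Sigma) m times,
# for tests that need exact control of the imputation distribution
fixed_draws <- function(mu, Sigma, arm, m) {
  structure(lapply(seq_len(m), function(k)
    list(mu = mu, Sigma = Sigma, arm = arm, index = k)),
    class = "cea_draws", arm = arm)
}

# moderate two-arm generator with MCAR missingness and exact-normal costs
mcar_config <- function(n = 500, dropout_logit = -2.08, cost_base = 0.05,
                        active_gain = c(0, 0.1, 0.1)) {
  schema <- simple_schema(Je = 3)
  mu0 <- c(q1 = 0.5, q2 = 0.55, q3 = 0.6, cost = 1000)
  mu1 <- mu0 + c(active_gain, 500)
  R <- matrix(c(1, .5, .4, -.1,
                .5, 1, .6, -.1,
                .4, .6, 1, -.1,
                -.1, -.1, -.1, 1), 4)
  sd <- c(.3, .3, .3, 400)
  S <- diag(sd) %*% R %*% diag(sd)
  dimnames(S) <- list(names(mu0), names(mu0))
  generator_config(schema, c(control = n, active = n),
                   means = list(control = mu0, active = mu1),
                   covariances = list(control = S, active = S),
                   mechanism = "MCAR",
                   dropout = list(intercepts = rep(dropout_logit, 2),
                                  slope = 0),
                   interim_rate = 0,
                   cost_missing = list(dropout = 1, interim = 0,
                                       complete = cost_base),
                   truncate_costs = FALSE)
}

# light sampler settings for tests: short burn-in is adequate because the
# data-augmentation chain for a low-dimensional MVN mixes in a few iterations
test_settings <- function(m = 20, burnin = 50, thin = 2, seed = NULL) {
  sampler_settings(m = m, burnin = burnin, thin = thin, seed = seed)
}
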