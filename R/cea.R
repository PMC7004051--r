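#' Quality-adjusted life-years by the area under the utility curve
#'
#' Trapezoidal integral of the utility trajectory, assuming linear change
#' between assessment points: `sum((t[j+1]-t[j]) * (y[j]+y[j+1]) / 2)`.
#' Computed only on complete trajectories (i.e. on imputed copies).
#'
#' @param qol numeric vector or matrix (participants x times) of utilities.
#' @param times assessment times in years, strictly increasing.
#' @return QALY value(s) over the horizon `times[1]..times[J]`.
#' @export
qaly_auc <- function(qol, times) {
  if (is.matrix(qol)) {
    if (ncol(qol) != length(times))
      stop("`qol` must have one column per assessment time")
    if (anyNA(qol)) stop("QALYs require complete utility trajectories")
    if (length(times) == 1) return(qol[, 1] * 0)
    w <- diff(times)
    drop((qol[, -ncol(qol), drop = FALSE] +
            qol[, -1, drop = FALSE]) %*% (w / 2))
  } else {
    qaly_auc(matrix(qol, nrow = 1), times)
  }
}

#' Incremental QALYs and costs from one completed dataset
#'
#' Unadjusted between-arm mean differences in effect and cost, with their
#' joint sampling covariance from the bivariate ("seemingly unrelated")
#' regression on the arm indicator.  With identical regressors in both
#' equations the SUR point estimates coincide with per-outcome least squares,
#' and the coefficient covariance is `(1/n0 + 1/n1)` times the pooled residual
#' covariance of (effect, cost).
#'
#' @param effect,cost numeric vectors (complete).
#' @param arm arm labels (exactly two levels).
#' @param comparator label of the comparator arm; differences are
#'   `other - comparator`.
#' @return List with `delta_e`, `delta_c`, `cov` (2x2 coefficient covariance,
#'   order effect then cost), arm means and sizes.
#' @export
estimate_incrementals <- function(effect, cost, arm, comparator) {
  if (anyNA(effect) || anyNA(cost))
    stop("incrementals are estimated on completed data only")
  arms <- unique(arm)
  if (length(arms) != 2) stop("exactly two arms are required")
  if (!comparator %in% arms) stop("comparator arm not found")
  trt <- setdiff(arms, comparator)
  i0 <- arm == comparator; i1 <- arm == trt
  n0 <- sum(i0); n1 <- sum(i1)
  de <- mean(effect[i1]) - mean(effect[i0])
  dc <- mean(cost[i1]) - mean(cost[i0])
  # pooled residual covariance after arm means (OLS residuals, n - 2 df)
  re <- effect - ifelse(i1, mean(effect[i1]), mean(effect[i0]))
  rc <- cost - ifelse(i1, mean(cost[i1]), mean(cost[i0]))
  S <- crossprod(cbind(re, rc)) / (n0 + n1 - 2)
  V <- (1 / n0 + 1 / n1) * S
  dimnames(V) <- list(c("effect", "cost"), c("effect", "cost"))
  list(delta_e = de, delta_c = dc, cov = V,
       mean0 = c(effect = mean(effect[i0]), cost = mean(cost[i0])),
       mean1 = c(effect = mean(effect[i1]), cost = mean(cost[i1])),
       n = c(n0 = n0, n1 = n1), arms = c(comparator, trt))
}

#' Pool estimates across imputed datasets by Rubin's rules
#'
#' For scalar estimates: pooled point `Qbar = mean(Q)`, within-imputation
#' variance `W = mean(U)`, between-imputation variance `B = var(Q)`, total
#' `T = W + (1 + 1/m) B`, degrees of freedom
#' `nu = (m - 1) (1 + W / ((1 + 1/m) B))^2`, and a 95% t interval.  When
#' `B = 0` the normal limit is used.  For vector estimates with covariance
#' matrices the same formulas pool componentwise and the covariance is
#' `Wbar + (1 + 1/m) B` with `B` the between-copy covariance.
#'
#' @param Q list (or vector) of per-copy estimates; scalars or vectors.
#' @param U list of per-copy variances (scalars) or covariance matrices.
#' @param conf confidence level for the interval (scalar case).
#' @return Object of class `cea_pooled`: `estimate`, `W`, `B`, `T` (variance
#'   or covariance matrix), `df`, `se`, `ci` (scalar case).
#' @export
rubin_pool <- function(Q, U, conf = 0.95) {
  if (is.list(Q) && length(Q[[1]]) > 1) {
    m <- length(Q)
    if (m < 2) stop("Rubin's rules require m >= 2 imputations")
    Qm <- do.call(rbind, Q)
    Qbar <- colMeans(Qm)
    W <- Reduce(`+`, U) / m
    B <- stats::cov(Qm)
    Tt <- W + (1 + 1 / m) * B
    return(structure(list(estimate = Qbar, W = W, B = B, T = Tt, m = m),
                     class = "cea_pooled"))
  }
  Q <- unlist(Q); U <- unlist(U)
  m <- length(Q)
  if (m < 2) stop("Rubin's rules require m >= 2 imputations")
  if (length(U) != m) stop("Q and U must have equal length")
  Qbar <- mean(Q)
  W <- mean(U)
  B <- stats::var(Q)
  Tt <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    q <- stats::qt(1 - (1 - conf) / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - (1 - conf) / 2)
  }
  se <- sqrt(Tt)
  structure(list(estimate = Qbar, W = W, B = B, T = Tt, df = df, se = se,
                 ci = c(Qbar - q * se, Qbar + q * se), m = m, conf = conf),
            class = "cea_pooled")
}

#' @export
print.cea_pooled <- function(x, ...) {
  if (length(x$estimate) > 1) {
    cat("Pooled estimates (m =", x$m, "):\n")
    print(x$estimate)
  } else {
    cat(sprintf("Pooled estimate %.4g (SE %.4g, %g%% CI %.4g to %.4g, df %.3g)\n",
                x$estimate, x$se, 100 * x$conf, x$ci[1], x$ci[2], x$df))
  }
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_c / delta_e`, in currency units per QALY.  Undefined when the QALY
#' difference is zero; a negative ratio (dominance quadrants) is returned with
#' a warning since it is not interpretable without the signs of its parts.
#'
#' @param delta_c pooled incremental cost.
#' @param delta_e pooled incremental effect (QALYs).
#' @return The ratio, or `NA` with a warning when `delta_e == 0`.
#' @export
icer <- function(delta_c, delta_e) {
  if (delta_e == 0) {
    warning("ICER undefined: incremental effect is zero")
    return(NA_real_)
  }
  r <- delta_c / delta_e
  if (r < 0)
    warning("negative ICER: interpret with the cost-effectiveness quadrant")
  r
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability that the
#' incremental net benefit `INB = lambda * delta_e - delta_c` is positive
#' under the normal approximation with
#' `var(INB) = lambda^2 var(de) + var(dc) - 2 lambda cov(de, dc)`.
#'
#' @param delta_e,delta_c pooled incremental effect and cost.
#' @param cov pooled 2x2 covariance of `(delta_e, delta_c)`.
#' @param lambda willingness-to-pay grid (default 0 to 50,000 by 500).
#' @return Data frame with `lambda`, `inb`, `se_inb`, `prob_ce`.
#' @export
ceac <- function(delta_e, delta_c, cov, lambda = seq(0, 50000, by = 500)) {
  cov <- as.matrix(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("pooled covariance of (delta_e, delta_c) is not positive semidefinite")
  inb <- lambda * delta_e - delta_c
  v <- lambda^2 * cov[1, 1] + cov[2, 2] - 2 * lambda * cov[1, 2]
  v <- pmax(v, 0)
  se <- sqrt(v)
  p <- ifelse(se > 0, stats::pnorm(inb / se), as.numeric(inb > 0))
  data.frame(lambda = lambda, inb = inb, se_inb = se, prob_ce = p)
}

#' Analyse multiply-imputed data: pooled CEA results
#'
#' Runs the economic evaluation on each completed copy (QALYs by
#' [qaly_auc()], incremental effects/costs by [estimate_incrementals()]) and
#' pools with Rubin's rules, returning per-arm pooled means, pooled
#' incrementals with t intervals, the ICER, and the acceptability curve.
#'
#' @param imputations an [impute()] result.
#' @param lambda willingness-to-pay grid for the CEAC.
#' @param lambda_star reporting threshold for "probability cost-effective".
#' @return Object of class `cea_result`.
#' @export
analyse_imputations <- function(imputations, lambda = seq(0, 50000, by = 500),
                                lambda_star = 20000) {
  data <- imputations$data
  schema <- data$schema
  if (length(schema$cost_vars) == 0)
    stop("CEA requires a cost endpoint in the schema")
  comparator <- schema$reference
  m <- imputations$m
  arms <- sort(unique(data$arm))
  trt <- setdiff(arms, comparator)

  per_copy <- lapply(imputations$datasets, function(Y) {
    qol <- Y[, schema$eff_vars, drop = FALSE]
    qaly <- qaly_auc(qol, schema$eff_times)
    cost <- rowSums(Y[, schema$cost_vars, drop = FALSE])
    inc <- estimate_incrementals(qaly, cost, data$arm, comparator)
    means <- lapply(stats::setNames(arms, arms), function(a) {
      rows <- data$arm == a
      vals <- cbind(qol[rows, , drop = FALSE], qaly = qaly[rows],
                    cost = cost[rows])
      list(mean = colMeans(vals),
           var_mean = apply(vals, 2, stats::var) / sum(rows))
    })
    list(inc = inc, means = means)
  })

  pool_arm <- function(a, stat) {
    Q <- lapply(per_copy, function(p) p$means[[a]]$mean[[stat]])
    U <- lapply(per_copy, function(p) p$means[[a]]$var_mean[[stat]])
    rubin_pool(Q, U)
  }
  stats_names <- c(schema$eff_vars, "qaly", "cost")
  arm_means <- lapply(stats::setNames(arms, arms), function(a)
    lapply(stats::setNames(stats_names, stats_names),
           function(s) pool_arm(a, s)))

  de <- rubin_pool(lapply(per_copy, function(p) p$inc$delta_e),
                   lapply(per_copy, function(p) p$inc$cov[1, 1]))
  dc <- rubin_pool(lapply(per_copy, function(p) p$inc$delta_c),
                   lapply(per_copy, function(p) p$inc$cov[2, 2]))
  joint <- rubin_pool(
    lapply(per_copy, function(p) c(p$inc$delta_e, p$inc$delta_c)),
    lapply(per_copy, function(p) p$inc$cov))

  curve <- ceac(joint$estimate[1], joint$estimate[2], joint$T, lambda)
  pstar <- ceac(joint$estimate[1], joint$estimate[2], joint$T,
                lambda_star)$prob_ce
  structure(list(
    arms = c(comparator = comparator, treatment = trt),
    arm_means = arm_means,
    delta_qaly = de, delta_cost = dc, pooled_cov = joint$T,
    icer = icer(dc$estimate, de$estimate),
    ceac = curve, lambda_star = lambda_star, prob_ce = pstar, m = m),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  fmt_ci <- function(p, digits = 3)
    sprintf("%.*f [%.*f, %.*f]", digits, p$estimate, digits, p$ci[1],
            digits, p$ci[2])
  cat("Cost-effectiveness analysis (", x$arms["treatment"], " vs ",
      x$arms["comparator"], ", m = ", x$m, " imputations)\n", sep = "")
  cat("  incremental QALYs:", fmt_ci(x$delta_qaly), "\n")
  cat("  incremental costs:", fmt_ci(x$delta_cost, 0), "\n")
  cat("  ICER:", format(round(x$icer), big.mark = ","), "per QALY\n")
  cat(sprintf("  P(cost-effective at %s): %.1f%%\n",
              format(x$lambda_star, big.mark = ","), 100 * x$prob_ce))
  invisible(x)
}

## Scenario names used in sensitivity suites and the mapping to endpoint
## assumptions.  "J2R-MAR" keeps costs MAR while QoL jumps to reference;
## "J2R-interim" additionally subjects interim-missing QoL to the jump;
## "BMCF" reverts post-dropout QoL to the baseline mean with costs MAR.
SCENARIOS <- list(
  "MAR"         = list(effectiveness = "MAR",  cost = "MAR", interim = "mar"),
  "J2R"         = list(effectiveness = "J2R",  cost = "J2R", interim = "mar"),
  "J2R-interim" = list(effectiveness = "J2R",  cost = "J2R",
                       interim = "dropout"),
  "J2R-MAR"     = list(effectiveness = "J2R",  cost = "MAR", interim = "mar"),
  "CIR"         = list(effectiveness = "CIR",  cost = "CIR", interim = "mar"),
  "LMCF"        = list(effectiveness = "LMCF", cost = "LMCF",
                       interim = "mar"),
  "BMCF"        = list(effectiveness = "BMCF", cost = "MAR", interim = "mar"))

scenario_assumptions <- function(name) {
  key <- names(SCENARIOS)[match(toupper(name), toupper(names(SCENARIOS)))]
  if (is.na(key))
    stop("unknown scenario '", name, "'; valid scenarios: ",
         paste(names(SCENARIOS), collapse = ", "))
  do.call(endpoint_assumptions, SCENARIOS[[key]])
}

#' Run a sensitivity suite of missing-data scenarios
#'
#' Fits the per-arm imputation model once, then imputes and analyses each
#' scenario with the *same* posterior draws and the same imputation noise
#' stream, so that differences between scenario results reflect the
#' assumptions rather than Monte-Carlo variation.
#'
#' @param data a [trial_data()] object (covariates complete).
#' @param scenarios character vector of scenario names; the default mirrors a
#'   typical sensitivity ladder from the primary MAR analysis to
#'   reference-based departures.
#' @param settings a [sampler_settings()].
#' @param seed master integer seed.
#' @param lambda,lambda_star CEAC grid and reporting threshold.
#' @return Object of class `cea_suite`: named list of [analyse_imputations()]
#'   results plus a `summary` data frame with one row per scenario
#'   (incremental QALYs and costs with CIs, ICER, probability cost-effective).
#' @export
run_sensitivity_suite <- function(data,
                                  scenarios = c("MAR", "J2R", "J2R-interim",
                                                "J2R-MAR", "BMCF"),
                                  settings = sampler_settings(), seed = 1L,
                                  lambda = seq(0, 50000, by = 500),
                                  lambda_star = 20000) {
  asms <- lapply(scenarios, scenario_assumptions)   # validate names up front
  draws <- fit_all_arms(data, settings, seed = seed)
  profile <- classify_missingness(data)
  imp_seed <- substream_seed(seed, "imputation")
  results <- vector("list", length(scenarios))
  names(results) <- scenarios
  for (k in seq_along(scenarios)) {
    imps <- impute(data, asms[[k]], draws, seed = imp_seed,
                   profile = profile)
    results[[k]] <- analyse_imputations(imps, lambda, lambda_star)
  }
  summary <- do.call(rbind, lapply(scenarios, function(s) {
    r <- results[[s]]
    data.frame(scenario = s,
               delta_qaly = r$delta_qaly$estimate,
               qaly_lo = r$delta_qaly$ci[1], qaly_hi = r$delta_qaly$ci[2],
               delta_cost = r$delta_cost$estimate,
               cost_lo = r$delta_cost$ci[1], cost_hi = r$delta_cost$ci[2],
               icer = r$icer, prob_ce = r$prob_ce,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary, seed = seed,
                 lambda_star = lambda_star),
            class = "cea_suite")
}

#' @export
print.cea_suite <- function(x, ...) {
  cat("Sensitivity suite (probability cost-effective at ",
      format(x$lambda_star, big.mark = ","), "):\n", sep = "")
  s <- x$summary
  out <- data.frame(
    scenario = s$scenario,
    `QALYs [95% CI]` = sprintf("%.3f [%.3f, %.3f]", s$delta_qaly, s$qaly_lo,
                               s$qaly_hi),
    `Costs [95% CI]` = sprintf("%.0f [%.0f, %.0f]", s$delta_cost, s$cost_lo,
                               s$cost_hi),
    ICER = format(round(s$icer), big.mark = ","),
    `P(CE)` = sprintf("%.1f%%", 100 * s$prob_ce),
    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
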