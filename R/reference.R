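ASSUMPTIONS <- c("MAR", "J2R", "CIR", "LMCF", "BMCF")

normalize_assumption <- function(x) {
  a <- toupper(trimws(x))
  if (!a %in% ASSUMPTIONS)
    stop("unknown assumption '", x, "'; valid choices: ",
         paste(ASSUMPTIONS, collapse = ", "))
  a
}

#' Missing-data assumptions per endpoint
#'
#' Pairs one imputation assumption for the effectiveness endpoint with one for
#' the cost endpoint, plus a policy for interim-missing values.  Each
#' assumption is one of:
#' \describe{
#'   \item{MAR}{missing at random: the randomised arm's distribution is used
#'     unchanged.}
#'   \item{J2R}{jump to reference: after dropout the conditional distribution
#'     switches to the reference arm's.}
#'   \item{CIR}{copy increments in reference: post-dropout means follow the
#'     reference arm's mean increments from the dropout point.}
#'   \item{LMCF}{last mean carried forward: post-dropout means stay at the
#'     randomised arm's mean at the dropout time.}
#'   \item{BMCF}{baseline mean carried forward: post-dropout means revert to
#'     the randomised arm's baseline mean.}
#' }
#' The two endpoints may differ only when at least one of them is MAR;
#' combining two *different* MNAR families is not supported.  BMCF on a cost
#' endpoint without a baseline cost measurement (a single total-cost variable)
#' falls back to MAR for costs, reflecting how the scenario is used in
#' practice when costs are not collected at baseline.
#'
#' @param effectiveness,cost assumption names (case-insensitive).
#' @param interim `"mar"` (default) treats interim-missing values as
#'   missing-at-random even when the endpoint is MNAR; `"dropout"` subjects
#'   them to the same reference-based rule as post-dropout values.
#' @return Object of class `cea_assumptions`.
#' @export
endpoint_assumptions <- function(effectiveness = "MAR", cost = "MAR",
                                 interim = c("mar", "dropout")) {
  eff <- normalize_assumption(effectiveness)
  cst <- normalize_assumption(cost)
  interim <- match.arg(interim)
  mnar <- setdiff(unique(c(eff, cst)), "MAR")
  if (length(mnar) > 1)
    stop("different MNAR families on the two endpoints (", eff, " + ", cst,
         ") are not supported; one endpoint must be MAR")
  structure(list(effectiveness = eff, cost = cst, interim = interim),
            class = "cea_assumptions")
}

#' @export
print.cea_assumptions <- function(x, ...) {
  cat("Assumptions: effectiveness ", x$effectiveness, ", cost ", x$cost,
      ", interim-missing treated as ",
      if (x$interim == "mar") "MAR" else "dropout", "\n", sep = "")
  invisible(x)
}

## Per-participant slice of a missingness profile (used by the builders).
profile_slice <- function(profile, i) {
  list(dropout = profile$dropout[i, ], interim = profile$interim[i, ],
       D_eff = profile$D_eff[i], D_cost = profile$D_cost[i])
}

## MNAR membership of each outcome variable for one participant under the
## given assumptions: dropout-missing cells of an MNAR endpoint always;
## interim-missing cells only under the treat-as-dropout policy.  BMCF on a
## single-variable cost endpoint degrades to MAR (no baseline cost).
mnar_flags <- function(assumptions, slice, schema) {
  Je <- length(schema$eff_vars); Jc <- length(schema$cost_vars)
  eff_a <- assumptions$effectiveness
  cost_a <- assumptions$cost
  if (cost_a == "BMCF" && Jc < 2) cost_a <- "MAR"
  f <- function(a, drop, inter) {
    if (a == "MAR") rep(FALSE, length(drop))
    else if (assumptions$interim == "dropout") drop | inter
    else drop
  }
  c(f(eff_a, slice$dropout[seq_len(Je)], slice$interim[seq_len(Je)]),
    f(cost_a, slice$dropout[Je + seq_len(Jc)],
      slice$interim[Je + seq_len(Jc)]))
}

## Mean entry for one MNAR-missing variable.  `anchor` is the index (within
## the endpoint's time ordering) of the last observed measurement before it,
## or 0 when nothing was observed earlier.
mnar_mean_entry <- function(assumption, j, anchor, mu_rand_e, mu_ref_e) {
  switch(assumption,
    MAR = mu_rand_e[j],
    J2R = mu_ref_e[j],
    CIR = if (anchor >= 1)
            mu_rand_e[anchor] + (mu_ref_e[j] - mu_ref_e[anchor])
          else mu_ref_e[j],
    LMCF = if (anchor >= 1) mu_rand_e[anchor] else mu_rand_e[j],
    BMCF = mu_rand_e[1])
}

#' Mean vector of the pattern-specific joint distribution
#'
#' Applies one assumption's mean rule to both endpoints of a participant's
#' variable vector.  Covariates and all entries up to the endpoint's dropout
#' index keep the randomised arm's means; later entries follow the
#' assumption (see [endpoint_assumptions()] for the rules).  Under the
#' `interim = "dropout"` policy, interim-missing entries are also switched,
#' anchored at the last observed measurement before them.
#'
#' @param assumption assumption name (applied to both endpoints; use
#'   [build_joint()] for differential assumptions).
#' @param mu_rand,mu_ref mean-vector draws for the randomised and reference
#'   arms (full schema ordering).  `mu_ref` may be `NULL` for MAR/LMCF/BMCF.
#' @param profile a [classify_missingness()] result.
#' @param i participant row index within `profile`.
#' @param schema the [trial_schema()].
#' @param interim interim-missing policy, `"mar"` or `"dropout"`.
#' @return Mean vector of the participant's pattern-specific joint.
#' @export
build_mean <- function(assumption, mu_rand, mu_ref = NULL, profile, i = 1L,
                       schema, interim = "mar") {
  assumption <- normalize_assumption(assumption)
  if (assumption %in% c("J2R", "CIR") && is.null(mu_ref))
    stop(assumption, " requires a reference-arm draw")
  asm <- endpoint_assumptions(assumption, assumption, interim)
  slice <- profile_slice(profile, i)
  build_mean_internal(asm, mu_rand, mu_ref, slice, schema)
}

build_mean_internal <- function(assumptions, mu_rand, mu_ref, slice, schema) {
  mu <- mu_rand
  mn <- mnar_flags(assumptions, slice, schema)
  if (!any(mn)) return(mu)
  Je <- length(schema$eff_vars); Jc <- length(schema$cost_vars)
  all_missing <- slice$dropout | slice$interim

  apply_endpoint <- function(mu, a, idx, miss_e, mn_e) {
    if (a == "MAR" || !any(mn_e)) return(mu)
    if (a == "BMCF" && length(idx) < 2) return(mu)   # no baseline: MAR
    obs_e <- !miss_e
    for (j in which(mn_e)) {
      anchor <- if (any(obs_e[seq_len(j - 1)]))
        max(which(obs_e[seq_len(j - 1)])) else 0L
      mu[idx[j]] <- mnar_mean_entry(a, j, anchor, mu_rand[idx],
                                    if (!is.null(mu_ref)) mu_ref[idx])
    }
    mu
  }
  mu <- apply_endpoint(mu, assumptions$effectiveness, eff_idx(schema),
                       all_missing[seq_len(Je)], mn[seq_len(Je)])
  cst_a <- assumptions$cost
  mu <- apply_endpoint(mu, cst_a, cost_idx(schema),
                       all_missing[Je + seq_len(Jc)], mn[Je + seq_len(Jc)])
  mu
}

#' Covariance of the pattern-specific joint under J2R / CIR
#'
#' Composes the joint covariance whose marginal over the pre-dropout block `P`
#' comes from the randomised arm and whose conditional law of the post-dropout
#' block `Q` given `P` comes from the reference arm.  With
#' `B = Sigma_ref[Q,P] Sigma_ref[P,P]^-1`:
#' \deqn{\tilde\Sigma_{PP} = \Sigma^{rand}_{PP},\quad
#'       \tilde\Sigma_{QP} = B\,\Sigma^{rand}_{PP},\quad
#'       \tilde\Sigma_{QQ} = \Sigma^{ref}_{QQ}
#'         - B(\Sigma^{ref}_{PP}-\Sigma^{rand}_{PP})B^\top.}
#' The same construction serves J2R and CIR (they differ only in the mean).
#' The result is returned in the original variable ordering and symmetrised.
#'
#' @param Sigma_rand,Sigma_ref positive-definite covariance draws for the two
#'   arms.
#' @param P integer indices of the block whose marginal is taken from the
#'   randomised arm (everything conditioned on).
#' @param Q integer indices of the block whose conditional law switches to the
#'   reference arm.  `P` and `Q` must partition the variables.
#' @param ridge ridge constant for near-singular `Sigma_ref[P,P]`.
#' @return The composed covariance matrix (symmetric, positive definite for
#'   positive-definite inputs).
#' @export
build_covariance_j2r_cir <- function(Sigma_rand, Sigma_ref, P, Q,
                                     ridge = 1e-8) {
  d <- nrow(Sigma_rand)
  if (!setequal(c(P, Q), seq_len(d)) || length(intersect(P, Q)))
    stop("P and Q must partition the variable indices")
  if (length(Q) == 0) return((Sigma_rand + t(Sigma_rand)) / 2)
  if (length(P) == 0) return((Sigma_ref + t(Sigma_ref)) / 2)
  out <- matrix(0, d, d, dimnames = dimnames(Sigma_rand))
  Spp_ref_inv <- chol2inv(chol_ridge(Sigma_ref[P, P, drop = FALSE], ridge,
                                     "reference pre-dropout block"))
  B <- Sigma_ref[Q, P, drop = FALSE] %*% Spp_ref_inv
  out[P, P] <- Sigma_rand[P, P]
  out[Q, P] <- B %*% Sigma_rand[P, P, drop = FALSE]
  out[P, Q] <- t(out[Q, P, drop = FALSE])
  out[Q, Q] <- Sigma_ref[Q, Q, drop = FALSE] -
    B %*% (Sigma_ref[P, P, drop = FALSE] -
             Sigma_rand[P, P, drop = FALSE]) %*% t(B)
  (out + t(out)) / 2
}

#' Assemble the pattern-specific joint distribution for one participant
#'
#' Splits the participant's missing variables into a missing-at-random block
#' (endpoints under MAR, plus interim-missing values under the `"mar"`
#' policy) and an MNAR block, then composes the joint: the marginal over
#' everything except the MNAR block is the randomised-arm draw, and the
#' conditional of the MNAR block given the rest follows the chosen assumption
#' (reference-arm conditional covariance for J2R/CIR; randomised-arm
#' covariance for MAR/LMCF/BMCF; means per the assumption's rule).
#'
#' @param assumptions an [endpoint_assumptions()] object.
#' @param draw_rand,draw_ref single posterior draws (elements of a
#'   `cea_draws` list) for the participant's randomised arm and the reference
#'   arm.  `draw_ref` may be `NULL` when no endpoint uses J2R/CIR.
#' @param profile a [classify_missingness()] result.
#' @param i participant row index.
#' @param schema the [trial_schema()].
#' @return Object of class `cea_pattern_joint`: `mean`, `cov`, and index sets
#'   `observed`, `mar_missing`, `mnar_missing` (into the joint vector).
#' @export
build_joint <- function(assumptions, draw_rand, draw_ref = NULL, profile,
                        i = 1L, schema) {
  needs_ref <- any(c(assumptions$effectiveness, assumptions$cost) %in%
                     c("J2R", "CIR"))
  if (needs_ref && is.null(draw_ref))
    stop("J2R/CIR assumptions require a reference-arm draw")
  slice <- profile_slice(profile, i)
  d <- schema_dim(schema)
  ncov <- length(schema$covariates)
  out_miss <- slice$dropout | slice$interim
  miss_idx <- ncov + which(out_miss)
  mn <- mnar_flags(assumptions, slice, schema)
  mnar_idx <- ncov + which(mn)
  mar_idx <- setdiff(miss_idx, mnar_idx)
  obs_idx <- setdiff(seq_len(d), miss_idx)

  mu <- build_mean_internal(assumptions, draw_rand$mu,
                            if (!is.null(draw_ref)) draw_ref$mu, slice,
                            schema)
  fam <- setdiff(unique(c(assumptions$effectiveness, assumptions$cost)),
                 "MAR")
  Sigma <- if (length(mnar_idx) && length(fam) && fam %in% c("J2R", "CIR")) {
    build_covariance_j2r_cir(draw_rand$Sigma, draw_ref$Sigma,
                             P = setdiff(seq_len(d), mnar_idx),
                             Q = mnar_idx)
  } else {
    (draw_rand$Sigma + t(draw_rand$Sigma)) / 2
  }
  structure(list(mean = mu, cov = Sigma, observed = obs_idx,
                 mar_missing = mar_idx, mnar_missing = mnar_idx),
            class = "cea_pattern_joint")
}
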