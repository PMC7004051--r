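#' Condition a multivariate normal on observed components
#'
#' Standard MVN conditioning: with observed block `P` and remaining block `Q`,
#' \deqn{m_{Q|P} = \mu_Q + \Sigma_{QP}\Sigma_{PP}^{-1}(y_P-\mu_P),\qquad
#'       S_{Q|P} = \Sigma_{QQ} - \Sigma_{QP}\Sigma_{PP}^{-1}\Sigma_{PQ}.}
#'
#' @param mean mean vector.
#' @param cov covariance matrix (positive definite on the observed block).
#' @param obs integer indices of the observed components (may be empty, in
#'   which case the marginal `(mean, cov)` is returned unchanged).
#' @param values observed values, same length as `obs`.
#' @return List with `mean` and `cov` of the remaining components, plus their
#'   indices `idx`.
#' @export
conditional_normal <- function(mean, cov, obs = integer(), values = numeric()) {
  d <- length(mean)
  obs <- as.integer(obs)
  if (length(obs) != length(values))
    stop("`obs` and `values` must have the same length")
  rest <- setdiff(seq_len(d), obs)
  if (length(obs) == 0)
    return(list(mean = mean, cov = cov, idx = rest))
  Spp <- cov[obs, obs, drop = FALSE]
  L <- tryCatch(chol(Spp), error = function(e)
    stop("observed block of the covariance is singular"))
  Spp_inv <- chol2inv(L)
  B <- cov[rest, obs, drop = FALSE] %*% Spp_inv
  m <- mean[rest] + drop(B %*% (values - mean[obs]))
  S <- cov[rest, rest, drop = FALSE] - B %*% cov[obs, rest, drop = FALSE]
  list(mean = m, cov = (S + t(S)) / 2, idx = rest)
}

## Order in which missing variables are drawn: MAR-missing block first with
## the cost endpoint ahead of effectiveness, then the MNAR block in schema
## order.  Sequential conditionals from the joint are exact in any order; this
## particular order makes the MAR-block draws (and hence, e.g., imputed costs
## when costs are MAR) reuse identical random deviates across scenarios run
## under a shared seed, so scenario differences are purely due to assumptions.
draw_order <- function(joint, schema) {
  mar <- joint$mar_missing
  ncov <- length(schema$covariates)
  is_cost <- mar > ncov + length(schema$eff_vars)
  c(mar[is_cost], mar[!is_cost], joint$mnar_missing)
}

#' Multiply impute missing outcomes under reference-based assumptions
#'
#' Runs Steps 3-5 of the reference-based algorithm: for each of the `m`
#' posterior draws and each participant with missing outcomes, builds the
#' pattern-specific joint ([build_joint()]), conditions it on the
#' participant's observed values and covariates, and draws the missing block
#' from the conditional normal.  Observed cells are never altered;
#' participants with complete data pass through untouched.
#'
#' Randomness is organised as one standard-normal deviate per (copy,
#' participant, variable), with the per-participant stream seeded from the
#' master seed and the participant identifier.  Results are therefore
#' invariant to participant order, and scenarios sharing `seed` and posterior
#' draws differ only through the assumption-specific distributions.
#'
#' @param data a [trial_data()] object.
#' @param assumptions an [endpoint_assumptions()] object.
#' @param draws named list of `cea_draws` (one per arm, equal length `m`),
#'   e.g. from [fit_all_arms()].
#' @param seed master integer seed for the imputation noise.
#' @param profile optional precomputed [classify_missingness()] result.
#' @return Object of class `cea_imputations`: list with `datasets` (length-`m`
#'   list of completed outcome matrices), `data`, `assumptions`, `m`, `seed`.
#' @export
impute <- function(data, assumptions, draws, seed = 1L, profile = NULL) {
  schema <- data$schema
  arms <- sort(unique(data$arm))
  if (!all(arms %in% names(draws)))
    stop("posterior draws missing for arm(s): ",
         paste(setdiff(arms, names(draws)), collapse = ", "))
  m <- unique(vapply(draws, length, 1L))
  if (length(m) != 1)
    stop("mismatched numbers of posterior draws between arms")
  if (is.null(profile)) profile <- classify_missingness(data)
  if (length(cov_idx(schema)) && any(data$mask[, cov_idx(schema)]))
    stop("covariates contain missing values; run impute_baseline_mean() first")

  d <- schema_dim(schema)
  ncov <- length(schema$covariates)
  nout <- d - ncov
  incomplete <- which(apply(data$mask, 1, any))

  ## group incomplete participants by (arm, outcome pattern): the joint and
  ## all conditional coefficients are shared within a group
  gkey <- paste(data$arm[incomplete], profile$signature[incomplete])
  groups <- split(incomplete, gkey)

  ## per-participant noise: z[i, v] ~ N(0,1) for outcome variable v, seeded
  ## from (seed, copy, id) so draws attach to variable identity, not order
  z_matrix <- function(copy, rows) {
    Z <- matrix(0, length(rows), nout)
    for (k in seq_along(rows)) {
      i <- rows[k]
      set.seed(participant_seed(seed, copy, data$id[i]))
      Z[k, ] <- stats::rnorm(nout)
    }
    Z
  }

  datasets <- vector("list", m)
  for (copy in seq_len(m)) {
    Yc <- data$Y
    for (g in groups) {
      i0 <- g[1]
      arm <- data$arm[i0]
      joint <- build_joint(assumptions, draws[[arm]][[copy]],
                           draws[[schema$reference]][[copy]],
                           profile, i0, schema)
      ord <- draw_order(joint, schema)
      Z <- z_matrix(copy, g)
      cond <- joint$observed
      for (v in ord) {
        Spp <- joint$cov[cond, cond, drop = FALSE]
        b <- drop(joint$cov[v, cond, drop = FALSE] %*%
                    chol2inv(chol_ridge(Spp, what = "observed block")))
        mv <- joint$mean[v] +
          drop(sweep(Yc[g, cond, drop = FALSE], 2,
                     joint$mean[cond]) %*% b)
        s2 <- joint$cov[v, v] - sum(b * joint$cov[cond, v])
        s2 <- max(s2, 0)
        Yc[g, v] <- mv + sqrt(s2) * Z[, v - ncov]
        cond <- c(cond, v)
      }
    }
    datasets[[copy]] <- Yc
  }
  structure(list(datasets = datasets, data = data,
                 assumptions = assumptions, m = m, seed = seed),
            class = "cea_imputations")
}

participant_seed <- function(seed, copy, id) {
  u <- utf8ToInt(as.character(id))
  h <- sum(u * (seq_along(u) %% 7 + 1) * 2654435.0) %% 2147483587
  as.integer((as.double(seed) * 69621 + as.double(copy) * 48271 + h) %%
               2147483587 + 1)
}

#' @export
print.cea_imputations <- function(x, ...) {
  cat("Multiply-imputed data: m =", x$m, "copies of",
      nrow(x$data$Y), "participants\n")
  print(x$assumptions)
  invisible(x)
}

#' Stack imputed datasets into one long data frame
#'
#' @param imputations a [impute()] result.
#' @param include_original prepend the original (incomplete) data as copy 0,
#'   the convention used by standard MI analysis tooling.
#' @return Data frame with a `.imp` copy-index column, id, arm and the schema
#'   columns.
#' @export
stack_imputations <- function(imputations, include_original = FALSE) {
  data <- imputations$data
  one <- function(k, Y) {
    df <- as.data.frame(Y)
    if (k == 0) df[data$mask] <- NA
    cbind(data.frame(.imp = k),
          stats::setNames(data.frame(data$id, data$arm,
                                     stringsAsFactors = FALSE),
                          c(data$schema$id_var %||% "id",
                            data$schema$arm_var)),
          df)
  }
  pieces <- lapply(seq_len(imputations$m),
                   function(k) one(k, imputations$datasets[[k]]))
  if (include_original)
    pieces <- c(list(one(0, data$Y)), pieces)
  do.call(rbind, pieces)
}
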