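#' Sampler settings for the multivariate-normal imputation model
#'
#' @param m number of retained posterior draws (one per imputed dataset);
#'   default 100, matching common multiple-imputation practice for
#'   cost-effectiveness data.
#' @param burnin data-augmentation iterations discarded before retention.
#' @param thin iterations between retained draws; with the default
#'   `burnin = 500`, `thin = 100` the retained draws are close to independent
#'   at the scale of a few hundred participants.
#' @param seed optional integer seed for the sampler.
#' @param ridge relative ridge constant: when a Cholesky factorisation fails,
#'   `ridge * trace(S)/d` is added to the diagonal.
#' @return An object of class `cea_sampler_settings`.
#' @export
sampler_settings <- function(m = 100, burnin = 500, thin = 100, seed = NULL,
                             ridge = 1e-8) {
  stopifnot(m >= 2, burnin >= 0, thin >= 1, ridge >= 0)
  structure(list(m = as.integer(m), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed, ridge = ridge,
                 prior = "jeffreys"),
            class = "cea_sampler_settings")
}

## Cholesky with ridge repair; errors if repair fails.
chol_ridge <- function(S, ridge = 1e-8, what = "covariance") {
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(L)) {
    d <- nrow(S)
    S <- S + diag(ridge * sum(diag(S)) / d, d)
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L))
      stop(what, " matrix is not positive definite after ridge repair")
  }
  L
}

## One draw from the Jeffreys-prior posterior given completed data:
## Sigma | Y ~ InvWishart(n - 1, S_c),  mu | Sigma, Y ~ N(ybar, Sigma / n)
draw_mu_sigma <- function(Yc, ridge) {
  n <- nrow(Yc); d <- ncol(Yc)
  ybar <- colMeans(Yc)
  Sc <- crossprod(sweep(Yc, 2, ybar))
  Sc <- (Sc + t(Sc)) / 2
  W <- stats::rWishart(1, df = n - 1, Sigma = chol2inv(chol_ridge(Sc, ridge)))[, , 1]
  Sigma <- chol2inv(chol_ridge(W, ridge))
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- ybar + drop(crossprod(chol_ridge(Sigma, ridge), stats::rnorm(d))) / sqrt(n)
  list(mu = mu, Sigma = Sigma)
}

#' Posterior draws of the per-arm multivariate normal model under MAR
#'
#' Fits, for one treatment arm, a multivariate normal model to the joint
#' vector (covariates, effectiveness by time, costs by time) using the
#' observed data under the missing-at-random assumption, and returns `m`
#' posterior draws of the mean vector and covariance matrix.  Arms are always
#' fitted separately; the reference-based joint distributions are assembled
#' later from one draw per arm.
#'
#' The sampler is a standard data-augmentation Gibbs scheme under the Jeffreys
#' prior `p(mu, Sigma) ~ |Sigma|^-(d+1)/2`:
#' \enumerate{
#'   \item initialise `(mu, Sigma)` from complete cases (falling back to
#'     available-case means and a ridge-regularised covariance when fewer than
#'     `d + 2` complete rows exist);
#'   \item impute every missing cell from its conditional normal given the
#'     current parameters (participants sharing a missingness pattern are
#'     updated together);
#'   \item draw `Sigma` from its inverse-Wishart full conditional and `mu`
#'     from its normal full conditional given the completed data;
#'   \item discard `burnin` iterations, then retain every `thin`-th state.
#' }
#'
#' @param data a [trial_data()] object (it may contain several arms; only
#'   `arm` is used).
#' @param arm label of the arm to fit.
#' @param settings a [sampler_settings()] object.
#' @return Object of class `cea_draws`: a list of `m` draws, each with
#'   elements `mu`, `Sigma`, `arm`, `index`; settings are kept as an
#'   attribute.  Covariates must be complete (see [impute_baseline_mean()])
#'   and every variable must be observed for at least two participants in the
#'   arm.
#' @export
fit_mvn_posterior <- function(data, arm, settings = sampler_settings()) {
  schema <- data$schema
  keep <- data$arm == arm
  if (!any(keep)) stop("no participants in arm '", arm, "'")
  Y <- data$Y[keep, , drop = FALSE]
  M <- data$mask[keep, , drop = FALSE]
  n <- nrow(Y); d <- ncol(Y)

  ccols <- cov_idx(schema)
  if (length(ccols) && any(M[, ccols]))
    stop("covariates contain missing values; run impute_baseline_mean() first")
  nobs <- colSums(!M)
  if (any(nobs < 2))
    stop("variable(s) observed for < 2 participants in arm '", arm, "': ",
         paste(colnames(Y)[nobs < 2], collapse = ", "))
  if (n - 1 < d)
    stop("arm '", arm, "' has too few participants (", n,
         ") for a ", d, "-dimensional model")

  if (!is.null(settings$seed)) set.seed(settings$seed)

  ## initial values from complete cases, else available-case + ridge
  cc <- !apply(M, 1, any)
  if (sum(cc) >= d + 2) {
    mu <- colMeans(Y[cc, , drop = FALSE])
    Sigma <- stats::cov(Y[cc, , drop = FALSE])
  } else {
    mu <- colMeans(Y, na.rm = TRUE)
    Sigma <- stats::cov(Y, use = "pairwise.complete.obs")
    Sigma[is.na(Sigma)] <- 0
    Sigma <- Sigma + diag(0.1 * mean(diag(Sigma)) + 1e-8, d)
  }
  Sigma <- (Sigma + t(Sigma)) / 2

  ## group incomplete rows by missingness pattern: the conditional
  ## coefficients are shared within a pattern, so each iteration costs a few
  ## small solves regardless of n
  sig <- apply(M, 1, function(r) paste0(as.integer(r), collapse = ""))
  inc <- which(apply(M, 1, any))
  groups <- if (length(inc)) split(inc, sig[inc]) else list()
  ginfo <- lapply(groups, function(rows) {
    mis <- which(M[rows[1], ])
    list(rows = rows, mis = mis, obs = setdiff(seq_len(d), mis))
  })

  Yc <- Y
  for (g in ginfo) Yc[g$rows, g$mis] <- 0   # placeholder, overwritten below

  impute_step <- function(Yc, mu, Sigma) {
    for (g in ginfo) {
      o <- g$obs; mi <- g$mis; rows <- g$rows
      if (length(o)) {
        B <- Sigma[mi, o, drop = FALSE] %*% chol2inv(chol_ridge(
          Sigma[o, o, drop = FALSE], settings$ridge))
        cm <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
          sweep(Yc[rows, o, drop = FALSE], 2, mu[o]) %*% t(B)
        S <- Sigma[mi, mi, drop = FALSE] - B %*% Sigma[o, mi, drop = FALSE]
      } else {
        cm <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE)
        S <- Sigma[mi, mi, drop = FALSE]
      }
      S <- (S + t(S)) / 2
      L <- chol_ridge(S, settings$ridge, "conditional covariance")
      Z <- matrix(stats::rnorm(length(rows) * length(mi)),
                  length(rows), length(mi))
      Yc[rows, mi] <- cm + Z %*% L
    }
    Yc
  }

  draws <- vector("list", settings$m)
  total <- settings$burnin + settings$m * settings$thin
  kept <- 0L
  for (it in seq_len(total)) {
    Yc <- impute_step(Yc, mu, Sigma)
    st <- draw_mu_sigma(Yc, settings$ridge)
    mu <- st$mu; Sigma <- st$Sigma
    if (it > settings$burnin &&
        (it - settings$burnin) %% settings$thin == 0) {
      kept <- kept + 1L
      names(mu) <- colnames(Y)
      dimnames(Sigma) <- list(colnames(Y), colnames(Y))
      draws[[kept]] <- list(mu = mu, Sigma = Sigma, arm = arm, index = kept)
    }
  }
  structure(draws, class = "cea_draws", arm = arm, settings = settings)
}

#' @export
print.cea_draws <- function(x, ...) {
  cat("Posterior draws: m =", length(x), "for arm '", attr(x, "arm"),
      "' (", length(x[[1]]$mu), "variables )\n")
  invisible(x)
}

#' Fit the imputation model for every arm
#'
#' Convenience wrapper running [fit_mvn_posterior()] for each arm with seeds
#' derived from a single master seed, so that downstream scenarios can share
#' identical posterior draws.
#'
#' @param data a [trial_data()] object.
#' @param settings a [sampler_settings()].
#' @param seed master integer seed.
#' @return Named list of `cea_draws`, one per arm.
#' @export
fit_all_arms <- function(data, settings = sampler_settings(), seed = NULL) {
  arms <- sort(unique(data$arm))
  out <- vector("list", length(arms))
  names(out) <- arms
  for (k in seq_along(arms)) {
    s <- settings
    if (!is.null(seed)) s$seed <- substream_seed(seed, "posterior", k)
    out[[k]] <- fit_mvn_posterior(data, arms[k], s)
  }
  out
}

## Deterministic 31-bit substream seeds derived from a master seed and a
## stream label, so every random component is reproducible and independent of
## evaluation order.
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  s <- (as.double(seed) * 48271 + h * 69621 + as.double(index) * 16807)
  as.integer(s %% 2147483587 + 1)
}
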