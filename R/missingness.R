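#' Classify missing outcome values as dropout- or interim-missing
#'
#' Within each endpoint (effectiveness, cost) a missing measurement is
#' *dropout*-missing when every later measurement of the same endpoint is also
#' missing, and *interim*-missing when at least one later measurement is
#' observed.  The dropout index `D` of an endpoint is the last time index with
#' an observed value (`D` equal to the number of assessments means no dropout).
#' Classification depends only on the missingness mask, never on the values,
#' and is tracked per endpoint because quality-of-life and cost measurements
#' need not share a missingness pattern.
#'
#' @param data a [trial_data()] object.
#' @return An object of class `cea_missingness` with elements:
#'   \describe{
#'     \item{dropout, interim}{logical matrices (participants x outcome
#'       variables) flagging dropout- and interim-missing cells.}
#'     \item{D_eff, D_cost}{integer vectors of per-endpoint dropout indices
#'       (0 = nothing observed).}
#'     \item{signature}{per-participant observed/missing pattern string over
#'       the outcome variables, `"o"` observed / `"m"` missing.}
#'     \item{table}{pattern-frequency data frame with per-arm and total
#'       counts.}
#'   }
#' @export
classify_missingness <- function(data) {
  schema <- data$schema
  out_vars <- schema_outcomes(schema)
  M <- data$mask[, out_vars, drop = FALSE]
  n <- nrow(M)
  Je <- length(schema$eff_vars)
  Jc <- length(schema$cost_vars)

  endpoint_split <- function(m) {
    # m: logical matrix over one endpoint's time-ordered columns
    J <- ncol(m)
    if (J == 0)
      return(list(D = integer(n), drop = m, inter = m))
    obs <- !m
    # last observed index per row; 0 when nothing observed
    D <- apply(obs, 1, function(r) if (any(r)) max(which(r)) else 0L)
    drop <- m & col(m) > D           # after the last observation
    inter <- m & !drop               # observed again later
    list(D = as.integer(D), drop = drop, inter = inter)
  }

  eff <- endpoint_split(M[, seq_len(Je), drop = FALSE])
  cst <- endpoint_split(M[, Je + seq_len(Jc), drop = FALSE])

  dropout <- cbind(eff$drop, cst$drop)
  interim <- cbind(eff$inter, cst$inter)
  colnames(dropout) <- colnames(interim) <- out_vars

  sig <- apply(M, 1, function(r) paste(ifelse(r, "m", "o"), collapse = ""))
  arms <- sort(unique(data$arm))
  tab <- table(factor(sig), factor(data$arm, levels = arms))
  ptab <- data.frame(pattern = rownames(tab),
                     as.data.frame.matrix(unclass(tab)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  ptab$total <- rowSums(tab)
  # completers first, then by decreasing frequency
  ptab <- ptab[order(ptab$pattern != strrep("o", ncol(M)), -ptab$total), ]
  rownames(ptab) <- NULL

  structure(list(dropout = dropout, interim = interim,
                 D_eff = eff$D, D_cost = cst$D,
                 signature = sig, table = ptab, n = n, arms = arms),
            class = "cea_missingness")
}

#' @export
print.cea_missingness <- function(x, ...) {
  cat("Missingness profile for", x$n, "participants\n")
  cat("  dropout-missing cells:", sum(x$dropout),
      " interim-missing cells:", sum(x$interim), "\n")
  print(pattern_percentages(x), row.names = FALSE)
  invisible(x)
}

#' Tabulate missing-data pattern frequencies and percentages
#'
#' Given either a missingness profile or a raw count table (e.g. pattern
#' counts transcribed from a trial report), returns counts and percentages per
#' arm and overall, percentages computed as `100 * count / N` and rounded to
#' one decimal for display (the unrounded values are kept in `pct_*_raw`
#' columns).
#'
#' @param x a `cea_missingness` object, or a data frame with a `pattern`
#'   column followed by one count column per arm (a `total` column is added if
#'   absent).
#' @return Data frame with `n_<arm>`, `pct_<arm>`, `n_total`, `pct_total`
#'   columns.
#' @export
pattern_percentages <- function(x) {
  tab <- if (inherits(x, "cea_missingness")) x$table else as.data.frame(x)
  if (!"pattern" %in% names(tab)) stop("count table needs a 'pattern' column")
  cnt_cols <- setdiff(names(tab), c("pattern", "total"))
  cnt <- as.matrix(tab[cnt_cols])
  if (!"total" %in% names(tab)) tab$total <- rowSums(cnt)
  out <- data.frame(pattern = tab$pattern, stringsAsFactors = FALSE)
  for (a in cnt_cols) {
    N <- sum(tab[[a]])
    if (N == 0) stop("arm '", a, "' has zero participants")
    out[[paste0("n_", a)]] <- tab[[a]]
    out[[paste0("pct_", a)]] <- round(100 * tab[[a]] / N, 1)
    out[[paste0("pct_", a, "_raw")]] <- 100 * tab[[a]] / N
  }
  N <- sum(tab$total)
  if (N == 0) stop("empty pattern table (N = 0)")
  out$n_total <- tab$total
  out$pct_total <- round(100 * tab$total / N, 1)
  out$pct_total_raw <- 100 * tab$total / N
  out
}
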