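#' Define the variable layout of a trial dataset
#'
#' A schema names the columns of a wide-format trial dataset and fixes the
#' ordering of the joint outcome vector used throughout the package:
#' covariates first, then the effectiveness (quality-of-life) measurements in
#' time order, then the cost measurements in time order.  All covariance
#' partitions and imputation draws reference this order.
#'
#' The two endpoints may have different numbers of assessment points; a single
#' total-cost variable is treated as a one-point cost endpoint located at the
#' final assessment time.  Assessment times are in years so that the
#' area-under-the-curve QALY has its conventional units.
#'
#' @param covariates character vector of fully observed baseline covariate
#'   column names (may be empty).
#' @param eff_vars character vector of effectiveness (utility) column names,
#'   one per assessment time, in time order.
#' @param eff_times numeric vector of assessment times in years, strictly
#'   increasing, same length as `eff_vars`.
#' @param cost_vars character vector of cost column names (may be empty for
#'   effectiveness-only problems).
#' @param cost_times numeric vector of cost assessment times in years.
#' @param arm_var name of the treatment-arm column.
#' @param reference label of the reference arm (usually the control arm);
#'   required by the J2R and CIR assumptions.
#' @param id_var optional name of a participant-identifier column.  When
#'   `NULL`, row numbers are used.
#'
#' @return An object of class `cea_schema`.
#' @examples
#' trial_schema(
#'   covariates = c("age", "sex", "bdi"),
#'   eff_vars   = c("qol_0", "qol_6", "qol_12"),
#'   eff_times  = c(0, 0.5, 1),
#'   cost_vars  = "cost_total",
#'   cost_times = 1,
#'   arm_var    = "arm",
#'   reference  = "usual care"
#' )
#' @export
trial_schema <- function(covariates = character(), eff_vars, eff_times,
                         cost_vars = character(), cost_times = numeric(),
                         arm_var = "arm", reference, id_var = NULL) {
  stopifnot(is.character(eff_vars), length(eff_vars) >= 1)
  if (length(eff_times) != length(eff_vars))
    stop("`eff_times` must have one entry per effectiveness variable")
  if (length(cost_times) != length(cost_vars))
    stop("`cost_times` must have one entry per cost variable")
  if (length(eff_times) > 1 && any(diff(eff_times) <= 0))
    stop("effectiveness assessment times must be strictly increasing")
  if (length(cost_times) > 1 && any(diff(cost_times) <= 0))
    stop("cost assessment times must be strictly increasing")
  all_names <- c(covariates, eff_vars, cost_vars, arm_var, id_var)
  if (anyDuplicated(all_names))
    stop("variable names in a schema must be unique")
  structure(
    list(covariates = as.character(covariates),
         eff_vars = as.character(eff_vars), eff_times = as.numeric(eff_times),
         cost_vars = as.character(cost_vars),
         cost_times = as.numeric(cost_times),
         arm_var = arm_var, reference = as.character(reference),
         id_var = id_var),
    class = "cea_schema")
}

#' @export
print.cea_schema <- function(x, ...) {
  cat("Trial schema\n")
  cat("  covariates:   ", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)", "\n")
  cat("  effectiveness:", paste(sprintf("%s@%gy", x$eff_vars, x$eff_times), collapse = ", "), "\n")
  cat("  cost:         ", if (length(x$cost_vars)) paste(sprintf("%s@%gy", x$cost_vars, x$cost_times), collapse = ", ") else "(none)", "\n")
  cat("  arm variable: ", x$arm_var, " (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

## ---- internal index helpers -------------------------------------------------
## The joint vector is [covariates | eff by time | cost by time]; everything
## downstream indexes into that order.

schema_vars <- function(schema) {
  c(schema$covariates, schema$eff_vars, schema$cost_vars)
}

schema_outcomes <- function(schema) c(schema$eff_vars, schema$cost_vars)

schema_dim <- function(schema) length(schema_vars(schema))

# indices of the effectiveness / cost blocks within the joint vector
eff_idx <- function(schema) {
  length(schema$covariates) + seq_along(schema$eff_vars)
}

cost_idx <- function(schema) {
  length(schema$covariates) + length(schema$eff_vars) +
    seq_along(schema$cost_vars)
}

cov_idx <- function(schema) seq_along(schema$covariates)

#' Read a schema from a YAML or JSON configuration file
#'
#' The file names the columns, assessment times (years), arm variable and
#' reference arm, e.g.
#' ```yaml
#' covariates: [age, sex, bdi]
#' effectiveness: {vars: [qol_0, qol_6, qol_12], times: [0, 0.5, 1]}
#' cost: {vars: [cost_total], times: [1]}
#' arm: {var: arm, reference: usual care}
#' id: id
#' ```
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [trial_schema()] object.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("effectiveness", "arm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("schema config is missing field(s): ", paste(miss, collapse = ", "))
  trial_schema(
    covariates = as.character(cfg$covariates %||% character()),
    eff_vars = cfg$effectiveness$vars, eff_times = cfg$effectiveness$times,
    cost_vars = as.character(cfg$cost$vars %||% character()),
    cost_times = as.numeric(cfg$cost$times %||% numeric()),
    arm_var = cfg$arm$var, reference = cfg$arm$reference,
    id_var = cfg$id %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
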