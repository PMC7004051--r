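#' Construct a trial dataset object
#'
#' Bundles the numeric outcome/covariate matrix, the treatment-arm labels and
#' an explicit missingness mask.  Columns follow the joint ordering of the
#' schema ([covariates | effectiveness | cost]); the mask is `TRUE` exactly
#' where a value is absent.
#'
#' @param Y numeric matrix (participants x variables) with `NA` for missing
#'   cells; column names must match the schema variables (any order).
#' @param arm character vector of arm labels, one per row.
#' @param schema a [trial_schema()].
#' @param id optional participant identifiers (default: row numbers).
#' @return An object of class `cea_trial` with elements `Y` (matrix, `NA` in
#'   masked cells), `mask` (logical matrix), `arm`, `id` and `schema`.
#' @export
trial_data <- function(Y, arm, schema, id = NULL) {
  vars <- schema_vars(schema)
  Y <- as.matrix(Y)
  if (!all(vars %in% colnames(Y)))
    stop("data is missing schema column(s): ",
         paste(setdiff(vars, colnames(Y)), collapse = ", "))
  Y <- Y[, vars, drop = FALSE]
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  arm <- as.character(arm)
  if (length(arm) != n) stop("`arm` must have one label per row")
  if (anyNA(arm) || any(!nzchar(arm)))
    stop("validation error: missing arm label for row(s) ",
         paste(which(is.na(arm) | !nzchar(arm)), collapse = ", "))
  arms <- unique(arm)
  if (length(arms) < 2)
    warning("only one arm present; comparative analyses will fail")
  if (!schema$reference %in% arms)
    stop("reference arm '", schema$reference, "' not present in the data")
  if (is.null(id)) id <- as.character(seq_len(n))
  structure(
    list(Y = Y, mask = is.na(Y), arm = arm, id = as.character(id),
         schema = schema),
    class = "cea_trial")
}

#' @export
print.cea_trial <- function(x, ...) {
  cat("Trial data: ", nrow(x$Y), " participants, ",
      ncol(x$Y), " variables\n", sep = "")
  tab <- table(x$arm)
  cat("  arms: ", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n", sep = "")
  cat("  missing cells: ", sum(x$mask), " (",
      format(100 * mean(x$mask), digits = 3), "% of matrix)\n", sep = "")
  invisible(x)
}

#' Read wide-format trial data from a delimited text file
#'
#' Expects one row per participant with a header row.  Empty cells, `NA` and
#' `.` (Stata convention) are read as missing.  Outcome and covariate columns
#' must be numeric; a non-numeric cell is reported with its row and column.
#'
#' @param path path to a CSV file.
#' @param schema a [trial_schema()] naming the columns.
#' @param sep field separator (default comma).
#' @return A [trial_data()] object; row order is preserved.
#' @export
read_trial <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop("data file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA", "."),
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  vars <- schema_vars(schema)
  need <- c(vars, schema$arm_var, schema$id_var)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: column(s) not found in ", path, ": ",
         paste(miss, collapse = ", "))
  Y <- matrix(NA_real_, nrow(df), length(vars), dimnames = list(NULL, vars))
  for (v in vars) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop("parse error: non-numeric value '", raw[bad[1]], "' in column '",
           v, "', row ", bad[1])
    Y[, v] <- num
  }
  arm <- df[[schema$arm_var]]
  if (anyNA(arm))
    stop("validation error: missing arm label in row(s) ",
         paste(which(is.na(arm)), collapse = ", "))
  id <- if (!is.null(schema$id_var)) df[[schema$id_var]] else NULL
  trial_data(Y, arm, schema, id = id)
}

#' Write trial data back to CSV
#'
#' Inverse of [read_trial()]: masked cells are written as empty fields, so
#' `read_trial(write_trial(x))` round-trips the matrix and mask exactly.
#'
#' @param data a `cea_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(data, path) {
  df <- as.data.frame(data$Y)
  df[data$mask] <- NA
  out <- cbind(stats::setNames(data.frame(data$id, data$arm,
                                          stringsAsFactors = FALSE),
                               c(data$schema$id_var %||% "id",
                                 data$schema$arm_var)),
               df)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert a trial object to a data frame
#'
#' @param x a `cea_trial`.
#' @param ... unused.
#' @return data frame with id, arm and the schema columns (`NA` where masked).
#' @export
as.data.frame.cea_trial <- function(x, ...) {
  df <- as.data.frame(x$Y)
  df[x$mask] <- NA
  cbind(stats::setNames(data.frame(x$id, x$arm, stringsAsFactors = FALSE),
                        c(x$schema$id_var %||% "id", x$schema$arm_var)),
        df)
}

#' Mean-impute a baseline variable
#'
#' Replaces missing entries of a fully pre-randomisation variable (a covariate
#' or the baseline effectiveness measurement) by the overall observed mean, and
#' clears the mask for those cells.  This mirrors the usual handling of the
#' occasional missing baseline measurement, which is treated as covariate-like
#' rather than imputed as an outcome.
#'
#' @param data a `cea_trial`.
#' @param variable name of a covariate or the first effectiveness variable.
#' @return The trial with the variable completed.
#' @export
impute_baseline_mean <- function(data, variable) {
  schema <- data$schema
  baseline_ok <- c(schema$covariates, schema$eff_vars[1])
  if (!variable %in% baseline_ok)
    stop("'", variable, "' is not a baseline covariate/measurement")
  v <- data$Y[, variable]
  if (all(is.na(v))) stop("variable '", variable, "' is entirely missing")
  if (!anyNA(v)) return(data)
  v[is.na(v)] <- mean(v, na.rm = TRUE)
  data$Y[, variable] <- v
  data$mask[, variable] <- FALSE
  data
}
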