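# Delimited-table input/output and small utilities.
#
# Plate tables:  plate_id, condition, wells_total, wells_positive, fraction_plated
# Loss tables:   clone_id, condition, wells_total, populated_wells,
#                sensitive_wells, nominal_lambda (optional)
# TSV by default; .csv files are comma-separated. UTF-8, header required.

plate_cols <- c("plate_id", "condition", "wells_total", "wells_positive",
                "fraction_plated")
loss_cols <- c("clone_id", "condition", "wells_total", "populated_wells",
               "sensitive_wells")

table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Validate and normalise a plate table; row-numbered messages on violation.
as_plate_table <- function(x) {
  if (!is.data.frame(x)) stop("a plate table must be a data.frame")
  missing_cols <- setdiff(plate_cols, names(x))
  if (length(missing_cols)) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[plate_cols]
  for (i in seq_len(nrow(x))) {
    W <- x$wells_total[i]
    k <- x$wells_positive[i]
    f <- x$fraction_plated[i]
    if (is.na(W) || W < 1 || W != round(W)) {
      stop(sprintf("row %d: wells_total must be a positive integer (got %s)",
                   i, format(W)))
    }
    if (is.na(k) || k < 0 || k > W || k != round(k)) {
      stop(sprintf(
        "row %d: wells_positive must be an integer in [0, wells_total] (got %s of %s)",
        i, format(k), format(W)))
    }
    if (is.na(f) || f <= 0 || f > 1) {
      stop(sprintf("row %d: fraction_plated must lie in (0, 1] (got %s)",
                   i, format(f)))
    }
  }
  x
}

# A design is a plate table without counts (wells_total + fraction_plated).
as_plate_design <- function(x) {
  if (!is.data.frame(x)) stop("a plate design must be a data.frame")
  need <- c("wells_total", "fraction_plated")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("plate design is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(x$wells_total >= 1),
            all(x$fraction_plated > 0), all(x$fraction_plated <= 1))
  x
}

as_loss_table <- function(x) {
  if (!is.data.frame(x)) stop("a loss table must be a data.frame")
  missing_cols <- setdiff(loss_cols, names(x))
  if (length(missing_cols)) {
    stop("loss table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"nominal_lambda" %in% names(x)) x$nominal_lambda <- NA_real_
  x <- x[c(loss_cols, "nominal_lambda")]
  for (i in seq_len(nrow(x))) {
    W <- x$wells_total[i]
    n <- x$populated_wells[i]
    s <- x$sensitive_wells[i]
    if (is.na(W) || W < 1 || W != round(W)) {
      stop(sprintf("row %d: wells_total must be a positive integer (got %s)",
                   i, format(W)))
    }
    if (is.na(n) || n < 0 || n > W || n != round(n)) {
      stop(sprintf(
        "row %d: populated_wells must be an integer in [0, wells_total] (got %s of %s)",
        i, format(n), format(W)))
    }
    if (is.na(s) || s < 0 || s > n || s != round(s)) {
      stop(sprintf(
        "row %d: sensitive_wells must be an integer in [0, populated_wells] (got %s of %s)",
        i, format(s), format(n)))
    }
    if (!is.na(x$nominal_lambda[i]) && x$nominal_lambda[i] <= 0) {
      stop(sprintf("row %d: nominal_lambda must be positive when present", i))
    }
  }
  x
}

#' Read a limiting-dilution plate table
#'
#' Reads a delimited text file (TSV, or CSV by `.csv` extension) with
#' columns `plate_id, condition, wells_total, wells_positive,
#' fraction_plated`, header required. Rows violating the model invariants
#' (e.g. more positive wells than wells) are rejected with a message naming
#' the row.
#'
#' @param path Path to the file.
#' @return A validated `data.frame` (possibly 0 rows).
#' @export
read_plate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_plate_table(x)
}

#' Read a replica-plating loss table
#'
#' Columns `clone_id, condition, wells_total, populated_wells,
#' sensitive_wells` and optionally `nominal_lambda`; otherwise as
#' [read_plate_table()].
#'
#' @param path Path to the file.
#' @return A validated `data.frame` with a `nominal_lambda` column
#'   (`NA` where absent).
#' @export
read_loss_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, header = TRUE, sep = table_sep(path),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  as_loss_table(x)
}

#' Write a plate or loss table
#'
#' Writes tab-separated text (comma-separated for `.csv` paths) that
#' [read_plate_table()] / [read_loss_table()] read back identically.
#'
#' @param x The table to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(x, path) {
  utils::write.table(as_plate_table(x), path, sep = table_sep(path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_plate_table
#' @export
write_loss_table <- function(x, path) {
  utils::write.table(as_loss_table(x), path, sep = table_sep(path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Accepts the [sim_config()] keys (`n_sims`, `lambda_grid_min`,
#' `lambda_grid_max`, `lambda_grid_points`, `ci_level`, `q_grid_step`,
#' `seed`); missing keys take their defaults, unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_sim_config(as.list(x))
}

#' Estimate a doubling time from a growth series
#'
#' Least-squares fit of `log2(density)` against time; the doubling time is
#' the reciprocal of the slope, with its standard error by the delta method
#' from the regression standard error of the slope.
#'
#' @param timepoints Times in hours (at least 3).
#' @param densities Cell densities (positive), same length.
#' @return An object of class `doubling_fit`: list with `doubling_h`, `se_h`
#'   and the underlying `lm` fit.
#' @examples
#' estimate_doubling_time(c(0, 10, 20), c(1, 2, 4))  # 10 h, SE 0
#' @export
estimate_doubling_time <- function(timepoints, densities) {
  stopifnot(length(timepoints) == length(densities))
  if (length(timepoints) < 3) stop("at least 3 timepoints are required")
  if (any(densities <= 0)) stop("densities must be positive")
  fit <- stats::lm(log2(densities) ~ timepoints)
  slope <- stats::coef(fit)[["timepoints"]]
  # suppressWarnings: an exactly exponential series triggers the
  # "essentially perfect fit" warning from summary.lm; SE 0 is the answer
  se_slope <- suppressWarnings(
    summary(fit)$coefficients["timepoints", "Std. Error"])
  if (slope <= 0) {
    warning("non-increasing series: estimated doubling time is not meaningful")
  } else if (slope * diff(range(timepoints)) < 1) {
    warning("series spans less than one doubling; estimate will be imprecise")
  }
  structure(
    list(doubling_h = 1 / slope, se_h = se_slope / slope^2, fit = fit),
    class = "doubling_fit"
  )
}

#' @export
print.doubling_fit <- function(x, ...) {
  cat(sprintf("Doubling time: %.2f h (SE %.2f h)\n", x$doubling_h, x$se_h))
  invisible(x)
}
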