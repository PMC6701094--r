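# Between-year reliability (RMSE / nRMSE) and trait-index association.

#' Paired two-year index table
#'
#' Pairs the per-cultivar values of one index (FWS or CLI) measured in a
#' reference year and a validation year. Cultivars missing either year are
#' dropped pairwise. Right-censored failure wind speeds ("> S_m") enter as
#' the value S_m itself; this is the only convention under which a cultivar
#' censored in both years contributes a zero difference, and it biases the
#' RMSE downward, which is why the censor flags are kept on the table.
#'
#' @param cultivar Cultivar identifiers.
#' @param x_ref Values in the reference (first) year.
#' @param x_val Values in the validation (second) year.
#' @param censored_ref,censored_val Logical censor flags per year (only
#'   meaningful for FWS); censored entries must already hold the value S_m.
#' @return A data frame of class `paired_year_table` with complete pairs
#'   only.
#' @export
paired_year_table <- function(cultivar, x_ref, x_val,
                              censored_ref = FALSE, censored_val = FALSE) {
  n <- length(cultivar)
  stopifnot(length(x_ref) == n, length(x_val) == n)
  censored_ref <- rep_len(censored_ref, n)
  censored_val <- rep_len(censored_val, n)
  complete <- is.finite(x_ref) & is.finite(x_val)
  if (!any(complete)) {
    stop("no complete cultivar pairs across the two years", call. = FALSE)
  }
  structure(data.frame(cultivar = as.character(cultivar)[complete],
                       x_ref = as.numeric(x_ref)[complete],
                       x_val = as.numeric(x_val)[complete],
                       censored_ref = censored_ref[complete],
                       censored_val = censored_val[complete]),
            class = c("paired_year_table", "data.frame"))
}

#' Root mean square difference between years
#'
#' `RMSE = sqrt(mean((x_val - x_ref)^2))` over the complete cultivar pairs,
#' in the units of the index.
#'
#' @param pairs A `paired_year_table`.
#' @return RMSE, same units as the paired values.
#' @export
year_rmse <- function(pairs) {
  stopifnot(inherits(pairs, "paired_year_table"), nrow(pairs) >= 1)
  sqrt(mean((pairs$x_val - pairs$x_ref)^2))
}

#' Normalized RMSE between years, in percent
#'
#' RMSE divided by the mean of the reference-year values, expressed in
#' percent. Used to grade the reliability of an index across years.
#'
#' @param pairs A `paired_year_table`.
#' @return nRMSE in percent.
#' @export
year_nrmse <- function(pairs) {
  ref_mean <- mean(pairs$x_ref)
  if (ref_mean <= 0) {
    stop("reference-year mean must be > 0 for nRMSE", call. = FALSE)
  }
  100 * year_rmse(pairs) / ref_mean
}

#' Grade a reliability level from its nRMSE
#'
#' Standard agronomic model-evaluation thresholds: excellent below 10%,
#' good from 10 to below 20%, acceptable from 20 to below 30%, poor at 30%
#' and above.
#'
#' @param nrmse nRMSE in percent, >= 0.
#' @return One of `"excellent"`, `"good"`, `"acceptable"`, `"poor"`.
#' @export
reliability_grade <- function(nrmse) {
  stopifnot(is.numeric(nrmse), length(nrmse) == 1L, is.finite(nrmse))
  if (nrmse < 0) stop("nRMSE must be >= 0", call. = FALSE)
  if (nrmse < 10) "excellent"
  else if (nrmse < 20) "good"
  else if (nrmse < 30) "acceptable"
  else "poor"
}

#' Reliability report for one index
#'
#' @param pairs A `paired_year_table`.
#' @param index Name of the index the pairs refer to (e.g. `"FWS"`).
#' @return A list of class `reliability_report` with fields `index`, `n`,
#'   `rmse`, `nrmse` (percent) and `grade`.
#' @export
reliability_report <- function(pairs, index = "index") {
  nr <- year_nrmse(pairs)
  structure(list(index = index, n = nrow(pairs), rmse = year_rmse(pairs),
                 nrmse = nr, grade = reliability_grade(nr)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("%s reliability over %d cultivar pairs: RMSE %.4g, nRMSE %.2f%% (%s)\n",
              x$index, x$n, x$rmse, x$nrmse, x$grade))
  invisible(x)
}

#' Pearson correlation with validation
#'
#' Sample Pearson correlation between two trait/index vectors over
#' cultivars, requiring at least three pairs and non-degenerate variance.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlation matrix of CLI and cultivar traits
#'
#' Pairwise Pearson correlations over cultivar means for the cumulative
#' lodging index and the trait-table columns (Young's modulus, maximum
#' bending load, maximum transverse displacement, plant height, plant
#' azimuthal deviation, leaf number, leaf inclination angle, ear number,
#' ear height, ear length). Cultivars with an incomplete row are dropped
#' with a warning. No multiple-testing correction is applied; raw
#' coefficients only.
#'
#' @param traits A `trait_table` (see [read_traits_csv()]).
#' @param cli Named numeric vector of per-cultivar CLI values; names must
#'   match `traits$cultivar`.
#' @return Symmetric correlation matrix with unit diagonal; rows/columns
#'   `CLI, YM, MBL, MTD, PH, PAD, LN, LIA, EN, EH, EL`.
#' @export
correlation_matrix <- function(traits, cli) {
  stopifnot(inherits(traits, "trait_table"), !is.null(names(cli)))
  abbr <- c("YM", "MBL", "MTD", "PH", "PAD", "LN", "LIA", "EN", "EH", "EL")
  m <- as.matrix(traits[paste0(TRAIT_NAMES, "_mean")])
  colnames(m) <- abbr
  cli_col <- cli[match(traits$cultivar, names(cli))]
  m <- cbind(CLI = as.numeric(cli_col), m)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("dropping %d cultivar(s) with incomplete rows: %s",
                    sum(!complete),
                    paste(traits$cultivar[!complete], collapse = ", ")),
            call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need >= 3 complete cultivars", call. = FALSE)
  stats::cor(m, method = "pearson")
}
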