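#' Paired predicted/measured series
#'
#' One validation series: predicted and measured values of a single
#' quantity (flow rate or one of the pressure taps) over a set of circuit
#' combinations, in shared units.
#'
#' @param predicted model predictions
#' @param measured bench/clinical measurements, same length and units
#' @param label series name, one of `"flow"`, `"P1"`, `"P2"`, `"P3"`
#' @param combo_id optional identifiers for the combinations
#' @return an object of class `paired_series`
#' @export
paired_series <- function(predicted, measured,
                          label = c("flow", "P1", "P2", "P3"),
                          combo_id = NULL) {
  label <- match.arg(label)
  predicted <- as.numeric(predicted); measured <- as.numeric(measured)
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must have equal length", call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(measured)) {
    stop("paired series must not contain missing values", call. = FALSE)
  }
  if (is.null(combo_id)) combo_id <- as.character(seq_along(predicted))
  structure(list(predicted = predicted, measured = measured, label = label,
                 combo_id = as.character(combo_id)),
            class = "paired_series")
}

#' Observed-on-predicted linear regression
#'
#' Ordinary least squares line of the measured values (y) on the predicted
#' values (x). A slope of 1 and intercept of 0 indicate perfect agreement.
#'
#' @param series a [paired_series]
#' @return list with `slope`, `intercept`, and `r2` (the regression
#'   R-squared), at full precision
#' @export
regress_observed_on_predicted <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  if (length(series$predicted) < 2L) {
    stop("insufficient data: need at least 2 pairs for regression",
         call. = FALSE)
  }
  if (length(unique(series$predicted)) < 2L) {
    stop("degenerate regression: all predicted values identical",
         call. = FALSE)
  }
  fit <- stats::lm(measured ~ predicted,
                   data = data.frame(predicted = series$predicted,
                                     measured = series$measured))
  cf <- stats::coef(fit)
  r2 <- if (stats::var(series$measured) == 0) {
    # constant measurements: perfect agreement only if predictions match
    if (all(series$predicted == series$measured)) 1 else 0
  } else {
    # a residual-free fit triggers a spurious precision warning from summary.lm
    suppressWarnings(summary(fit))$r.squared
  }
  list(slope = unname(cf["predicted"]), intercept = unname(cf["(Intercept)"]),
       r2 = r2)
}

#' Agreement statistics between predicted and measured values
#'
#' Computes the validation summary for one series: R-squared, root mean
#' square deviation, bias (predicted minus measured; median and IQR),
#' median signed relative error, and the observed-on-predicted regression
#' slope/intercept.
#'
#' Conventions: `bias_i = predicted_i - measured_i`;
#' `relative error_i = (measured_i - predicted_i) / measured_i * 100` (so a
#' model that under-reads the measurements gives negative bias and positive
#' relative error); quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7). The headline `r2` is the
#' observed-on-predicted regression R-squared; `r2_identity`, the variant
#' computed about the y = x line (1 - SSres/SStot with residuals taken
#' against the predictions), is reported alongside for transparency.
#'
#' @param series a [paired_series]
#' @return an object of class `validation_report`: list with `label`, `n`,
#'   `r2`, `r2_identity`, `rmsd`, `bias_median`, `bias_q1`, `bias_q3`,
#'   `rel_err_median`, `slope`, `intercept`
#' @export
compute_validation_stats <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  pred <- series$predicted; meas <- series$measured
  if (length(pred) < 2L) {
    stop("insufficient data: need at least 2 pairs", call. = FALSE)
  }
  zero <- which(meas == 0)
  if (length(zero) > 0L) {
    stop(sprintf("relative error undefined: measured value is zero for combo %s",
                 paste(series$combo_id[zero], collapse = ", ")),
         call. = FALSE)
  }
  bias <- pred - meas
  rel_err <- (meas - pred) / meas * 100
  rmsd <- sqrt(mean((pred - meas)^2))
  reg <- regress_observed_on_predicted(series)
  ss_tot <- sum((meas - mean(meas))^2)
  r2_identity <- if (ss_tot == 0 && rmsd == 0) 1
                 else 1 - sum((meas - pred)^2) / ss_tot
  bq <- stats::quantile(bias, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    label = series$label, n = length(pred),
    r2 = reg$r2, r2_identity = r2_identity, rmsd = rmsd,
    bias_median = bq[2], bias_q1 = bq[1], bias_q3 = bq[3],
    rel_err_median = stats::median(rel_err),
    slope = reg$slope, intercept = reg$intercept
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation [%s], n = %d\n", x$label, x$n))
  cat(sprintf("  R^2 %.3f  RMSD %.3f  bias %.2f (%.2f, %.2f)  rel err %.2f%%\n",
              x$r2, x$rmsd, x$bias_median, x$bias_q1, x$bias_q3,
              x$rel_err_median))
  cat(sprintf("  observed-on-predicted: slope %.5f, intercept %.5f\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(label = x$label, n = x$n, r2 = x$r2,
             r2_identity = x$r2_identity, rmsd = x$rmsd,
             bias_median = x$bias_median, bias_q1 = x$bias_q1,
             bias_q3 = x$bias_q3, rel_err_median = x$rel_err_median,
             slope = x$slope, intercept = x$intercept,
             stringsAsFactors = FALSE)
}
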