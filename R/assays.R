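#' Radical-scavenging percentage from absorbance readings
#'
#' For both the DPPH (517 nm) and ABTS (734 nm) colorimetric assays the
#' scavenging activity is
#' \deqn{\%scavenging = (1 - (A_2 - A_0)/A_1) \times 100,}
#' where `A2` is the absorbance of sample plus radical reagent, `A0` is
#' the sample blank (sample plus solvent in place of the reagent) and
#' `A1` is the reagent-only control. `A2 = A0` gives 100% scavenging;
#' `A2 = A0 + A1` gives 0%.
#'
#' @param A0,A1,A2 Absorbance readings (vectorized); `A1` must be
#'   strictly positive.
#' @return Scavenging percentage(s).
#' @export
#' @examples
#' scavenging_percent(A0 = 0.05, A1 = 0.80, A2 = 0.45)  # 50
scavenging_percent <- function(A0, A1, A2) {
  if (any(A0 < 0) || any(A1 < 0) || any(A2 < 0))
    stop("absorbances must be nonnegative")
  if (any(A1 == 0)) stop("A1 (reagent-only control) must be positive")
  (1 - (A2 - A0) / A1) * 100
}

#' Read an assay plate CSV
#'
#' Expected columns: `concentration` (mg/mL), `A0`, `A1`, `A2` and
#' `assay` (one of `DPPH`, `ABTS`). A `scavenging_pct` column is
#' appended.
#'
#' @param path CSV file path.
#' @return A data.frame with the computed scavenging percentages.
#' @export
read_assay <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("concentration", "A0", "A1", "A2", "assay")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assay CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$assay), c("DPPH", "ABTS"))
  if (length(bad)) stop("unknown assay type(s): ", paste(bad, collapse = ", "))
  df$scavenging_pct <- scavenging_percent(df$A0, df$A1, df$A2)
  df
}

#' Fit a linear calibration curve
#'
#' Simple least-squares line signal = slope * concentration + intercept,
#' with r-squared and the calibrated concentration range recorded for
#' out-of-range warnings.
#'
#' @param concentrations Strictly increasing vector of standard
#'   concentrations (mg/mL), length >= 3.
#' @param signals Measured signals (e.g. peak areas) at those
#'   concentrations.
#' @return A `calibration_line`: `slope`, `intercept`, `r2`,
#'   `valid_range`.
#' @export
#' @examples
#' fit_calibration(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1, r2 1
fit_calibration <- function(concentrations, signals) {
  if (length(concentrations) < 3L) stop("need at least 3 calibration points")
  if (length(signals) != length(concentrations)) stop("length mismatch")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  fit <- stats::lm.fit(cbind(1, concentrations), signals)
  fitted <- signals - fit$residuals
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((signals - mean(signals))^2)
  calibration_line(slope = fit$coefficients[2L],
                   intercept = fit$coefficients[1L],
                   r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                   valid_range = range(concentrations))
}

#' Construct a calibration line from known parameters
#'
#' Useful for lines published without their underlying standards data.
#'
#' @param slope,intercept Line parameters (signal on concentration).
#' @param r2 Coefficient of determination in \[0, 1\].
#' @param valid_range Length-2 numeric, the calibrated concentration
#'   range (low < high), mg/mL.
#' @return A `calibration_line` object.
#' @export
calibration_line <- function(slope, intercept, r2 = NA_real_,
                             valid_range = c(-Inf, Inf)) {
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must be in [0, 1]")
  if (valid_range[1L] >= valid_range[2L])
    stop("valid_range must satisfy low < high")
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 r2 = as.numeric(r2), valid_range = as.numeric(valid_range)),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration: signal = %.4g * conc %+.4g (r2 = %s), range %g-%g mg/mL\n",
              x$slope, x$intercept,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
              x$valid_range[1L], x$valid_range[2L]))
  invisible(x)
}

#' Invert a calibration line
#'
#' Converts a measured signal to concentration,
#' `(signal - intercept) / slope`. Signals mapping outside the line's
#' calibrated range raise a warning (extrapolation), not an error.
#'
#' @param line A `calibration_line` with nonzero slope.
#' @param signal Measured signal(s).
#' @return Concentration(s) in mg/mL.
#' @export
concentration_from_signal <- function(line, signal) {
  stopifnot(inherits(line, "calibration_line"))
  if (line$slope == 0) stop("calibration slope is zero; line is not invertible")
  conc <- (signal - line$intercept) / line$slope
  out_of_range <- conc < line$valid_range[1L] | conc > line$valid_range[2L]
  if (any(out_of_range))
    warning(sprintf("%d value(s) outside calibrated range [%g, %g] mg/mL",
                    sum(out_of_range), line$valid_range[1L], line$valid_range[2L]))
  conc
}
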