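# Signal-intensity <-> gas-concentration calibration: quadratic fit,
# monotone inversion with LOD flagging, and LOD/LOQ bookkeeping.
#
# The instrument response is nonlinear (adsorption saturates at low
# concentration), so the curve is a second-order polynomial
# signal = c0 + c1 x + c2 x^2 over the measured standards range.

#' Construct a calibration curve
#'
#' @param c0,c1,c2 polynomial coefficients (signal units, x in ppbv).
#' @param valid_range numeric length-2, the ppbv range spanned by the
#'   standards; inversion is trusted here (plus a 10% margin).
#' @param lod,loq detection and quantification limits, ppbv. Defaults are
#'   the study-instrument values 0.04 and 0.12.
#' @param r_squared fit quality of the calibration regression.
#' @param analyte_mz metadata: mass-to-charge ratio of the monitored ion
#'   (default 177.6, the propofol ion).
#' @return An object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(c0, c1, c2, valid_range,
                              lod = 0.04, loq = 0.12,
                              r_squared = NA_real_, analyte_mz = 177.6) {
  stopifnot_number(c0, "c0"); stopifnot_number(c1, "c1"); stopifnot_number(c2, "c2")
  if (c1 <= 0) {
    b2p_stop("b2p_calibration_error", "linear coefficient c1 must be positive")
  }
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    b2p_stop("b2p_invalid_argument", "valid_range must be an increasing pair")
  }
  stopifnot_number(lod, "lod", positive = TRUE)
  stopifnot_number(loq, "loq", positive = TRUE)
  if (lod >= loq) {
    b2p_stop("b2p_invalid_argument", "lod must be below loq")
  }
  # strictly increasing on the valid range: derivative c1 + 2 c2 x > 0
  dmin <- min(c1 + 2 * c2 * valid_range)
  if (dmin <= 0) {
    b2p_stop("b2p_calibration_error",
             "calibration curve is not strictly increasing over its range")
  }
  structure(
    list(c0 = c0, c1 = c1, c2 = c2,
         valid_range = as.numeric(valid_range),
         lod = lod, loq = loq, r_squared = r_squared,
         analyte_mz = analyte_mz),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> signal = %.6g + %.6g x + %.6g x^2 (x in ppbv)\n",
              x$c0, x$c1, x$c2))
  cat(sprintf("  range [%g, %g] ppbv, LOD %g, LOQ %g, R^2 %s, m/z %g\n",
              x$valid_range[1], x$valid_range[2], x$lod, x$loq,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$analyte_mz))
  invisible(x)
}

#' Fit a quadratic calibration curve to standards
#'
#' Ordinary least-squares fit of `signal ~ concentration + concentration^2`.
#'
#' @param standards data.frame with columns `concentration_ppbv` and
#'   `signal_intensity` (or an unnamed two-column matrix in that order).
#'   At least 4 distinct concentrations are required.
#' @param lod,loq stored detection/quantification limits, ppbv (the limits
#'   are instrument properties, not derivable from the standards alone;
#'   see [estimate_lod()] for a blank-based estimator).
#' @return A [calibration_curve()] with `r_squared` and
#'   `valid_range = range(standards)`.
#' @export
fit_calibration <- function(standards, lod = 0.04, loq = 0.12) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration_ppbv", "signal_intensity") %in% names(standards))) {
    if (ncol(standards) == 2L) {
      names(standards) <- c("concentration_ppbv", "signal_intensity")
    } else {
      b2p_stop("b2p_calibration_error",
               "standards need columns concentration_ppbv, signal_intensity")
    }
  }
  x <- standards$concentration_ppbv
  y <- standards$signal_intensity
  if (length(unique(x)) < 4L) {
    b2p_stop("b2p_calibration_error",
             "at least 4 distinct standard concentrations required")
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  calibration_curve(cf[1], cf[2], cf[3], valid_range = range(x),
                    lod = lod, loq = loq, r_squared = r2)
}

#' Blank-based LOD/LOQ estimate
#'
#' Standard 3-sigma / 10-sigma rule: `(mean(blank) - c0 + k * sd(blank))`
#' divided by the slope at the origin (`c1`), with `k = 3` for the LOD and
#' `k = 10` for the LOQ.
#'
#' @param curve a [calibration_curve()].
#' @param blank_signals numeric vector of blank-measurement intensities.
#' @return A list with `lod` and `loq` in ppbv.
#' @export
estimate_lod <- function(curve, blank_signals) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(blank_signals) < 3L) {
    b2p_stop("b2p_calibration_error", "need >= 3 blank measurements")
  }
  m <- mean(blank_signals); s <- stats::sd(blank_signals)
  list(lod = (m - curve$c0 + 3 * s) / curve$c1,
       loq = (m - curve$c0 + 10 * s) / curve$c1)
}

#' Invert a calibration curve: signal to concentration
#'
#' Solves `c0 + c1 x + c2 x^2 = signal` for the physical (positive) root
#' `x = (-c1 + sqrt(c1^2 - 4 c2 (c0 - signal))) / (2 c2)` (plain linear
#' inversion when `c2 = 0`). Signals below the curve's intercept invert
#' to negative concentrations; those are clamped to 0 and flagged.
#' Concentrations up to 10% beyond the standards range are returned with
#' a warning; farther extrapolation is refused.
#'
#' @param curve a [calibration_curve()].
#' @param signal numeric vector of signal intensities.
#' @return A data.frame with columns `concentration_ppbv` and
#'   `below_lod` (logical).
#' @export
signal_to_concentration <- function(curve, signal) {
  stopifnot(inherits(curve, "calibration_curve"))
  x <- if (curve$c2 == 0) {
    (signal - curve$c0) / curve$c1
  } else {
    disc <- curve$c1^2 - 4 * curve$c2 * (curve$c0 - signal)
    if (any(disc < 0)) {
      b2p_stop("b2p_out_of_range",
               "signal outside the invertible range of the quadratic")
    }
    (-curve$c1 + sqrt(disc)) / (2 * curve$c2)
  }
  below <- x < curve$lod
  x[x < 0] <- 0
  span <- diff(curve$valid_range)
  hard_hi <- curve$valid_range[2] + 0.1 * span
  if (any(x > hard_hi)) {
    b2p_stop("b2p_out_of_range", sprintf(
      "inverted concentration %.4g ppbv is > 10%% beyond the calibrated range [%g, %g]",
      max(x), curve$valid_range[1], curve$valid_range[2]))
  }
  if (any(x > curve$valid_range[2])) {
    b2p_warn("b2p_extrapolation", "inverting beyond the calibrated range (<= 10%)")
  }
  data.frame(concentration_ppbv = x, below_lod = below)
}

#' Forward-evaluate a calibration curve
#'
#' @param curve a [calibration_curve()].
#' @param concentration_ppbv numeric vector.
#' @return Predicted signal intensities.
#' @export
concentration_to_signal <- function(curve, concentration_ppbv) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$c0 + curve$c1 * concentration_ppbv + curve$c2 * concentration_ppbv^2
}

#' Serialise / deserialise a calibration curve as JSON
#' @param curve a [calibration_curve()].
#' @param path file path.
#' @return `read_calibration_json` returns a [calibration_curve()];
#'   `write_calibration_json` returns `path` invisibly.
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(c0 = curve$c0, c1 = curve$c1, c2 = curve$c2,
              lod_ppbv = curve$lod, loq_ppbv = curve$loq,
              r_squared = curve$r_squared,
              range = curve$valid_range, analyte_mz = curve$analyte_mz)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_curve(obj$c0, obj$c1, obj$c2, valid_range = obj$range,
                    lod = obj$lod_ppbv, loq = obj$loq_ppbv,
                    r_squared = obj$r_squared, analyte_mz = obj$analyte_mz)
}
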