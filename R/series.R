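# Concentration time-series container, the LOD censoring rule, and
# breath-plasma pairing for the agreement stage.

SERIES_UNITS <- c("ppbv", "pptv", "ug/mL", "ng/mL")
CENSOR_FLAGS <- c("observed", "below_lod_zeroed", "excluded")

#' Create a concentration time series
#'
#' One subject's time course in one matrix (exhaled breath or plasma).
#' Values carry a per-point censor flag: `"observed"`,
#' `"below_lod_zeroed"` (sub-LOD before the peak, value set to 0 but
#' retained), or `"excluded"` (sub-LOD at/after the peak, dropped from
#' fitting and pairing but kept for the audit trail).
#'
#' @param subject_id character or integer identifier.
#' @param matrix `"breath"` or `"plasma"`.
#' @param times sampling times in minutes, strictly increasing.
#' @param values concentrations in `unit`; non-negative where observed.
#' @param unit one of `"ppbv"`, `"pptv"`, `"ug/mL"`, `"ng/mL"`.
#' @param censored optional character vector of per-point flags; defaults
#'   to all `"observed"`.
#' @param group optional group label carried through reports.
#'
#' @return An object of class `"concentration_series"`.
#' @export
concentration_series <- function(subject_id, matrix, times, values,
                                 unit, censored = NULL, group = NA_character_) {
  matrix <- match.arg(matrix, c("breath", "plasma"))
  unit <- match.arg(unit, SERIES_UNITS)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    b2p_stop("b2p_invalid_argument", "times and values must have equal length")
  }
  if (length(times) == 0L) {
    b2p_stop("b2p_data_error", "empty concentration series")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    b2p_stop("b2p_data_error", "times must be strictly increasing")
  }
  if (is.null(censored)) censored <- rep("observed", length(times))
  if (!all(censored %in% CENSOR_FLAGS)) {
    b2p_stop("b2p_invalid_argument", sprintf(
      "censor flags must be in {%s}", paste(CENSOR_FLAGS, collapse = ", ")))
  }
  if (any(values < 0 & censored == "observed")) {
    b2p_stop("b2p_data_error", "observed concentrations must be non-negative")
  }
  structure(
    list(subject_id = as.character(subject_id), matrix = matrix,
         times = times, values = values, unit = unit,
         censored = censored, group = group),
    class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> subject %s, %s (%s), %d points on [%g, %g] min\n",
              x$subject_id, x$matrix, x$unit, length(x$times),
              min(x$times), max(x$times)))
  n_z <- sum(x$censored == "below_lod_zeroed")
  n_e <- sum(x$censored == "excluded")
  if (n_z + n_e > 0) cat(sprintf("  censored: %d zeroed, %d excluded\n", n_z, n_e))
  invisible(x)
}

#' Apply the sub-LOD censoring rule
#'
#' Points below the detection limit are treated as 0 before the peak is
#' reached and as not detectable (excluded) from the peak onwards. "The
#' peak" is the argmax of the raw, pre-censoring values; on ties the
#' earliest maximum is used. Excluded points keep their row (flag
#' `"excluded"`) so that writing the series back out preserves an exact
#' audit trail.
#'
#' @param series a [concentration_series()].
#' @param lod detection limit, in the series' own unit.
#' @return The series with updated `values`/`censored`.
#' @export
censor_series <- function(series, lod) {
  stopifnot(inherits(series, "concentration_series"))
  stopifnot_number(lod, "lod", nonneg = TRUE)
  i_max <- which.max(series$values)  # earliest argmax of the raw curve
  below <- series$values < lod & series$censored == "observed"
  pre <- below & seq_along(series$values) < i_max
  post <- below & seq_along(series$values) >= i_max
  series$values[pre] <- 0
  series$censored[pre] <- "below_lod_zeroed"
  series$censored[post] <- "excluded"
  series
}

#' Convert between gas-phase and plasma concentration units
#'
#' Supported pairs: ppbv <-> pptv and ug/mL <-> ng/mL (factor 1000 each
#' way). Identity conversions are allowed.
#'
#' @param value numeric vector.
#' @param from_unit,to_unit unit strings.
#' @return Converted numeric vector.
#' @examples
#' convert_units(5.87, "ppbv", "pptv")  # 5870
#' @export
convert_units <- function(value, from_unit, to_unit) {
  key <- paste(from_unit, to_unit, sep = "->")
  factor <- switch(key,
    "ppbv->pptv" = 1000, "pptv->ppbv" = 1 / 1000,
    "ug/mL->ng/mL" = 1000, "ng/mL->ug/mL" = 1 / 1000,
    "ppbv->ppbv" = 1, "pptv->pptv" = 1,
    "ug/mL->ug/mL" = 1, "ng/mL->ng/mL" = 1,
    NULL)
  if (is.null(factor)) {
    b2p_stop("b2p_unit_error", sprintf("unsupported unit conversion %s", key))
  }
  value * factor
}

#' Pair breath with plasma observations by time
#'
#' Anchored on the plasma schedule (the sparse matrix): for each retained,
#' positive plasma point, the nearest retained breath point within
#' `tolerance` minutes is selected (earlier point on a distance tie).
#' Pre-dose points and censored/zero values never pair. Output
#' concentrations are normalised to pptv (breath) and ng/mL (plasma), the
#' units used by the log-log stage.
#'
#' @param breath,plasma censored [concentration_series()] objects.
#' @param tolerance maximal time separation, minutes. Default 1/6 min
#'   (half the 20-s breath sampling interval) so at most one breath bin
#'   can match each blood draw.
#' @return A data.frame with columns `time`, `ce` (pptv), `cp` (ng/mL).
#' @export
pair_matrices <- function(breath, plasma, tolerance = 1 / 6) {
  stopifnot(inherits(breath, "concentration_series"),
            inherits(plasma, "concentration_series"))
  stopifnot_number(tolerance, "tolerance", nonneg = TRUE)
  if (breath$matrix != "breath" || plasma$matrix != "plasma") {
    b2p_stop("b2p_invalid_argument",
             "arguments must be a breath series and a plasma series")
  }
  bu <- breath$censored == "observed" & breath$values > 0 & breath$times > 0
  pu <- plasma$censored == "observed" & plasma$values > 0 & plasma$times > 0
  bt <- breath$times[bu]
  bv <- convert_units(breath$values[bu], breath$unit,
                      if (breath$unit %in% c("ppbv", "pptv")) "pptv" else "ng/mL")
  pt <- plasma$times[pu]
  pv <- convert_units(plasma$values[pu], plasma$unit,
                      if (plasma$unit %in% c("ug/mL", "ng/mL")) "ng/mL" else "pptv")
  rows <- lapply(seq_along(pt), function(i) {
    if (length(bt) == 0L) return(NULL)
    d <- abs(bt - pt[i])
    j <- which(d == min(d))[1]  # earliest on tie
    if (d[j] > tolerance + 1e-12) return(NULL)
    data.frame(time = pt[i], ce = bv[j], cp = pv[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    b2p_stop("b2p_pairing_error", "no breath-plasma pairs within tolerance")
  }
  out
}
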