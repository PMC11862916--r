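# Domain types for compartmental pharmacokinetics: dose events and
# micro/macro parameter sets, as lightweight validated S3 lists.

#' Create a dose event
#'
#' Describes a single intravenous administration. `duration = 0` denotes an
#' instantaneous bolus; `duration > 0` denotes a zero-order (constant-rate)
#' infusion of that length.
#'
#' @param amount drug mass administered, mg. Must be positive.
#' @param start_time start of administration, minutes (default 0).
#' @param duration infusion duration in minutes; 0 means bolus.
#'
#' @return An object of class `"dose_event"`.
#' @examples
#' dose_event(4.76)              # bolus, Group-BM-sized dose
#' dose_event(7.63, duration = 0.95)  # ~1-min constant-rate infusion
#' @export
dose_event <- function(amount, start_time = 0, duration = 0) {
  stopifnot_number(amount, "amount", positive = TRUE)
  stopifnot_number(start_time, "start_time", nonneg = TRUE)
  stopifnot_number(duration, "duration", nonneg = TRUE)
  structure(
    list(amount = amount, start_time = start_time, duration = duration),
    class = "dose_event"
  )
}

#' Create a compartmental micro-parameter set
#'
#' Micro rate constants of a mammillary 1-, 2- or 3-compartment model:
#' `V1` is the apparent central volume (mg per concentration unit), `K10`
#' the first-order elimination rate from the central compartment, and
#' `K12`/`K21` (and `K13`/`K31` for three compartments) the central to/from
#' peripheral exchange rates, all in 1/min.
#'
#' @param V1 central volume of distribution, mg/(conc unit).
#' @param K10 elimination rate constant, 1/min.
#' @param K12,K21 exchange rates with the first peripheral compartment,
#'   1/min. Omit (`NULL`) for a one-compartment model.
#' @param K13,K31 exchange rates with the second peripheral compartment,
#'   1/min. Supply both for a three-compartment model.
#'
#' @return An object of class `"micro_params"` with an `n_compartments`
#'   field inferred from which rates are present.
#' @examples
#' micro_params(V1 = 0.21, K10 = 0.25, K12 = 0.13, K21 = 0.03)
#' @export
micro_params <- function(V1, K10, K12 = NULL, K21 = NULL,
                         K13 = NULL, K31 = NULL) {
  stopifnot_number(V1, "V1", positive = TRUE)
  stopifnot_number(K10, "K10", positive = TRUE)
  has12 <- !is.null(K12) || !is.null(K21)
  has13 <- !is.null(K13) || !is.null(K31)
  if (has12) {
    stopifnot_number(K12, "K12", positive = TRUE)
    stopifnot_number(K21, "K21", positive = TRUE)
  }
  if (has13) {
    if (!has12) {
      b2p_stop("b2p_invalid_argument",
               "K13/K31 require K12/K21 (no skipped peripheral compartment)")
    }
    stopifnot_number(K13, "K13", positive = TRUE)
    stopifnot_number(K31, "K31", positive = TRUE)
  }
  n_cpt <- 1L + has12 + has13
  unn <- function(x) if (is.null(x)) NULL else unname(x)
  structure(
    list(n_compartments = n_cpt, V1 = unname(V1), K10 = unname(K10),
         K12 = unn(K12), K21 = unn(K21), K13 = unn(K13), K31 = unn(K31)),
    class = "micro_params"
  )
}

#' Create a macro (poly-exponential) parameter set
#'
#' The observable form of a linear mammillary model after a bolus:
#' `C(t) = sum_i coefficients[i] * exp(-exponents[i] * t)`. For a
#' two-compartment model the convention is `(A, alpha)` and `(B, beta)`
#' with `alpha > beta`.
#'
#' @param coefficients amplitudes `A_i`, concentration units.
#' @param exponents decay rates `lambda_i` in 1/min; must be strictly
#'   positive and distinct. Stored sorted descending together with their
#'   coefficients.
#'
#' @return An object of class `"macro_params"`.
#' @examples
#' macro_params(c(22.01, 0.659), c(0.3908, 0.01919))
#' @export
macro_params <- function(coefficients, exponents) {
  if (length(coefficients) != length(exponents)) {
    b2p_stop("b2p_invalid_argument",
             "coefficients and exponents must have equal length")
  }
  if (!length(exponents) %in% 1:3) {
    b2p_stop("b2p_invalid_argument", "1 to 3 exponential terms supported")
  }
  if (any(!is.finite(coefficients)) || any(!is.finite(exponents))) {
    b2p_stop("b2p_invalid_argument", "macro parameters must be finite")
  }
  if (any(exponents <= 0)) {
    b2p_stop("b2p_invalid_argument", "exponents must be strictly positive")
  }
  if (anyDuplicated(exponents)) {
    b2p_stop("b2p_degenerate_model", "exponents must be distinct")
  }
  ord <- order(exponents, decreasing = TRUE)
  structure(
    list(n_compartments = length(exponents),
         coefficients = as.numeric(coefficients[ord]),
         exponents = as.numeric(exponents[ord])),
    class = "macro_params"
  )
}

#' @export
print.dose_event <- function(x, ...) {
  kind <- if (x$duration == 0) "bolus" else sprintf("infusion over %g min", x$duration)
  cat(sprintf("<dose_event> %.4g mg %s at t = %g min\n", x$amount, kind, x$start_time))
  invisible(x)
}

#' @export
print.micro_params <- function(x, ...) {
  cat(sprintf("<micro_params> %d-compartment\n", x$n_compartments))
  cat(sprintf("  V1 = %.4g, K10 = %.4g", x$V1, x$K10))
  if (x$n_compartments >= 2L) cat(sprintf(", K12 = %.4g, K21 = %.4g", x$K12, x$K21))
  if (x$n_compartments == 3L) cat(sprintf(", K13 = %.4g, K31 = %.4g", x$K13, x$K31))
  cat("\n")
  invisible(x)
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf("<macro_params> %d terms\n", x$n_compartments))
  for (i in seq_along(x$exponents)) {
    cat(sprintf("  %.5g * exp(-%.5g t)\n", x$coefficients[i], x$exponents[i]))
  }
  invisible(x)
}
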