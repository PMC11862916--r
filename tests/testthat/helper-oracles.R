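# Independent oracles used by the tests. These deliberately avoid the
# package's closed-form code paths: concentrations come from a fixed-step
# RK4 integration of the compartment amount ODEs, ICC mean squares from
# stats::aov, and AUC from trapezoids on a dense grid.

# RK4 integration of
#   dA1/dt = -(K10+K12+K13) A1 + K21 A2 + K31 A3
#   dA2/dt =  K12 A1 - K21 A2
#   dA3/dt =  K13 A1 - K31 A3
# with a bolus A1(0) = dose; returns A1/V1 at the requested times.
ode_concentration <- function(mp, dose_amount, times, h = 0.02) {
  k10 <- mp$K10
  k12 <- if (is.null(mp$K12)) 0 else mp$K12
  k21 <- if (is.null(mp$K21)) 0 else mp$K21
  k13 <- if (is.null(mp$K13)) 0 else mp$K13
  k31 <- if (is.null(mp$K31)) 0 else mp$K31
  deriv <- function(a) c(
    -(k10 + k12 + k13) * a[1] + k21 * a[2] + k31 * a[3],
    k12 * a[1] - k21 * a[2],
    k13 * a[1] - k31 * a[3])
  a <- c(dose_amount, 0, 0)
  tcur <- 0
  out <- numeric(length(times))
  for (idx in order(times)) {
    tt <- times[idx]
    if (tt > tcur) {
      n <- max(1L, ceiling((tt - tcur) / h))
      hh <- (tt - tcur) / n
      for (i in seq_len(n)) {
        k1 <- deriv(a)
        k2 <- deriv(a + hh / 2 * k1)
        k3 <- deriv(a + hh / 2 * k2)
        k4 <- deriv(a + hh * k3)
        a <- a + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      tcur <- tt
    }
    out[idx] <- a[1] / mp$V1
  }
  out
}

# two-way ANOVA mean squares via stats::aov, then the absolute-agreement
# single-measure ICC formula (k = 2 raters)
icc_oracle <- function(actual, predicted) {
  n <- length(actual)
  df <- data.frame(
    v = c(actual, predicted),
    subj = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n)))
  ms <- stats::anova(stats::aov(v ~ subj + rater, data = df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

trapezoid_auc <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Table-style micro parameter sets used across tests (plasma columns of
# the study's parameter table, plus the high-dose breath column)
BM_PLASMA <- list(V1 = 0.21, K10 = 0.25, K12 = 0.13, K21 = 0.03, dose = 4.76)
BH_BREATH <- list(V1 = 0.24, K10 = 0.11, K12 = 0.14, K21 = 0.10, dose = 7.63)
PLASMA_TIMES <- c(1, 3, 5, 10, 20, 30, 60, 90, 120)
BREATH_TIMES <- seq(1 / 3, 120, by = 1 / 3)

noiseless_series <- function(pars, times, matrix = "plasma",
                             unit = if (matrix == "plasma") "ug/mL" else "ppbv") {
  mp <- micro_params(V1 = pars$V1, K10 = pars$K10, K12 = pars$K12, K21 = pars$K21)
  d <- dose_event(pars$dose)
  v <- predict_concentration(micro_to_macro(mp, d), d, times)
  concentration_series("oracle", matrix, times, v, unit)
}

random_micro2 <- function() {
  micro_params(
    V1 = stats::runif(1, 0.1, 1),
    K10 = stats::runif(1, 0.05, 0.5),
    K12 = stats::runif(1, 0.05, 0.3),
    K21 = stats::runif(1, 0.01, 0.2))
}
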