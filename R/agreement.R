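# Correlation, log-log regression, breath-based plasma prediction, and
# agreement statistics: ICC (two-way, absolute agreement, single measure),
# Bland-Altman limits of agreement, one-way ANOVA and matrix t-tests.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive mean ranks), with a
#' p-value from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param pairs data.frame with columns `ce` and `cp` (as produced by
#'   [pair_matrices()]), or any two-column numeric data.
#' @return A list with `r`, `p_value`, `n`.
#' @export
spearman_correlation <- function(pairs) {
  xy <- extract_xy(pairs)
  n <- length(xy$x)
  if (n < 3L) b2p_stop("b2p_data_error", "need >= 3 pairs")
  rx <- rank(xy$x); ry <- rank(xy$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    b2p_stop("b2p_undefined_correlation", "constant input: correlation undefined")
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

extract_xy <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (all(c("ce", "cp") %in% names(pairs))) {
    list(x = pairs$ce, y = pairs$cp)
  } else if (ncol(pairs) >= 2L) {
    list(x = pairs[[1]], y = pairs[[2]])
  } else {
    b2p_stop("b2p_invalid_argument", "pairs must have two numeric columns")
  }
}

#' Fit the log-log breath-plasma link
#'
#' Ordinary least squares of `LN(cp)` on `LN(ce)`. Units are fixed by
#' convention to pptv for breath and ng/mL for plasma -- the scales on
#' which the overall study regression `LN(Cp) = 1.42 LN(Ce) - 1.70` is
#' expressed -- so predictions are only meaningful when inputs follow the
#' same convention.
#'
#' @param pairs data.frame with positive columns `ce` (pptv) and `cp`
#'   (ng/mL); at least 3 rows.
#' @return An object of class `"loglog_model"`: `slope`, `intercept`,
#'   `r_squared`, `n_pairs`, `ce_unit`, `cp_unit`.
#' @export
fit_loglog <- function(pairs) {
  xy <- extract_xy(pairs)
  if (length(xy$x) < 3L) b2p_stop("b2p_regression_error", "need >= 3 pairs")
  if (any(xy$x <= 0) || any(xy$y <= 0)) {
    b2p_stop("b2p_regression_error", "log-log fit requires strictly positive pairs")
  }
  lx <- log(xy$x); ly <- log(xy$y)
  if (stats::sd(lx) == 0) {
    b2p_stop("b2p_regression_error", "zero variance in LN(ce)")
  }
  fit <- stats::lm(ly ~ lx)
  # R^2 computed directly (summary.lm warns on numerically perfect fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_pairs = length(lx),
         ce_unit = "pptv", cp_unit = "ng/mL"),
    class = "loglog_model")
}

#' @export
print.loglog_model <- function(x, ...) {
  cat(sprintf("<loglog_model> LN(cp) = %.4g * LN(ce) %+.4g  (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_pairs))
  cat(sprintf("  units: ce in %s, cp in %s\n", x$ce_unit, x$cp_unit))
  invisible(x)
}

#' Predict plasma concentration from a breath concentration
#'
#' `cp = exp(slope * ln(ce) + intercept)` on the model's unit convention.
#'
#' @param model a `"loglog_model"`.
#' @param ce breath concentration(s), pptv; must be positive.
#' @return Predicted plasma concentration(s), ng/mL.
#' @export
predict_plasma <- function(model, ce) {
  stopifnot(inherits(model, "loglog_model"))
  if (any(ce <= 0)) {
    b2p_stop("b2p_domain_error", "breath concentration must be positive")
  }
  exp(model$slope * log(ce) + model$intercept)
}

#' Agreement between measured and predicted values
#'
#' Intraclass correlation of the two-way, absolute-agreement, single-measure
#' form, computed from the ANOVA mean squares of the n x 2 table (subjects
#' as rows, the two measurement sets as columns):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`.
#' The p-value and 95% CI follow the standard F-based construction for
#' this ICC form. Bland-Altman fields are computed on the raw differences
#' `predicted - actual` (set `log_scale = TRUE` for log-scale differences):
#' `bias` is their mean, the limits of agreement `bias +/- 1.96 sd`.
#'
#' @param actual,predicted numeric vectors of equal length >= 3.
#' @param log_scale compute Bland-Altman on log-transformed values.
#' @param conf_level confidence level for the ICC interval.
#' @return A list: `icc`, `icc_ci` (length 2), `p_value`, `bias`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
icc_agreement <- function(actual, predicted, log_scale = FALSE,
                          conf_level = 0.95) {
  if (length(actual) != length(predicted)) {
    b2p_stop("b2p_invalid_argument", "actual and predicted must match in length")
  }
  n <- length(actual)
  if (n < 3L) b2p_stop("b2p_data_error", "need >= 3 paired values")
  X <- cbind(actual, predicted)
  k <- 2L
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((sweep(sweep(X, 1, row_m), 2, col_m) + grand)^2)
  sst <- sum((X - grand)^2)
  if (sst == 0) b2p_stop("b2p_undefined_icc", "zero total variance")
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom
  # F test and CI (McGraw & Wong A,1 form); degenerate when MSE == 0
  if (mse == 0 && msc == 0) {
    p <- 0; ci <- c(1, 1)
  } else {
    fv <- msr / mse
    p <- stats::pf(fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
    alpha <- 1 - conf_level
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  d <- if (log_scale) {
    if (any(X <= 0)) b2p_stop("b2p_domain_error", "log-scale agreement needs positive values")
    log(predicted) - log(actual)
  } else {
    predicted - actual
  }
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(icc = icc, icc_ci = ci, p_value = p,
       bias = bias, loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
       n = n, log_scale = log_scale)
}

#' One-way analysis of variance
#'
#' `F = MSB / MSW` with between/within degrees of freedom
#' `(g - 1, N - g)`; p from the F distribution.
#'
#' @param groups a named or unnamed list of numeric vectors (>= 2 groups,
#'   each with >= 2 values).
#' @return A list: `statistic` (F), `p_value`, `df` (length 2),
#'   `groups` (names).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    b2p_stop("b2p_invalid_argument", "need a list of >= 2 groups")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    b2p_stop("b2p_invalid_argument", "each group needs >= 2 values")
  }
  all_v <- unlist(groups, use.names = FALSE)
  grand <- mean(all_v)
  N <- length(all_v); g <- length(groups)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  if (ssw == 0 && ssb == 0) {
    b2p_stop("b2p_degenerate", "no variance between or within groups")
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (N - g)
  f <- if (msw == 0) Inf else msb / msw
  p <- stats::pf(f, g - 1, N - g, lower.tail = FALSE)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_along(groups))
  list(statistic = f, p_value = p, df = c(g - 1, N - g), groups = nms)
}

# parameters whose units differ between matrices (mg per ppbv vs mg per
# ug/mL), so cross-matrix comparison is meaningless and refused
INCOMMENSURABLE_PARAMS <- c("V1", "CL", "AUC", "AUC_0_120", "auc_0_T", "auc_inf", "cl")

#' Compare a PK parameter between breath and plasma fits
#'
#' Paired t-test (default; the same animals yield both matrices) or
#' unpaired Welch t-test of per-subject parameter values. Comparisons of
#' `V1`, `CL` and AUC are refused: their units embed the matrix's
#' concentration unit, so breath and plasma values are incommensurable.
#'
#' @param ce_values,cp_values numeric vectors of per-subject parameter
#'   values from the breath and plasma fits (subject-aligned when paired).
#' @param parameter parameter name, e.g. `"K10"`, `"t_half_beta"`.
#' @param paired logical; paired by subject (default) or Welch.
#' @return A list: `statistic` (t), `p_value`, `df`, `parameter`, `paired`.
#' @export
compare_parameters <- function(ce_values, cp_values, parameter,
                               paired = TRUE) {
  if (parameter %in% INCOMMENSURABLE_PARAMS) {
    b2p_stop("b2p_refused_comparison", sprintf(
      "comparison of %s between matrices is refused (unit-incommensurable)",
      parameter))
  }
  if (paired && length(ce_values) != length(cp_values)) {
    b2p_stop("b2p_invalid_argument", "paired comparison needs aligned vectors")
  }
  tt <- if (paired) {
    d <- ce_values - cp_values
    n <- length(d)
    if (n < 2L) b2p_stop("b2p_data_error", "paired t-test needs >= 2 pairs")
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      # degenerate: identical differences everywhere
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      list(statistic = stat, p.value = if (stat == 0) 1 else 0,
           parameter = n - 1)
    } else {
      stat <- mean(d) / (sd_d / sqrt(n))
      list(statistic = stat,
           p.value = 2 * stats::pt(-abs(stat), df = n - 1),
           parameter = n - 1)
    }
  } else {
    res <- stats::t.test(ce_values, cp_values, paired = FALSE, var.equal = FALSE)
    list(statistic = unname(res$statistic), p.value = res$p.value,
         parameter = unname(res$parameter))
  }
  list(statistic = tt$statistic, p_value = tt$p.value, df = tt$parameter,
       parameter = parameter, paired = paired)
}
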