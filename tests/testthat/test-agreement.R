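# Agreement statistics: Spearman, log-log regression, prediction, ICC,
# Bland-Altman, ANOVA and the matrix t-test with its refusal rule.

test_that("spearman correlation handles monotone data and ties", {
  up <- data.frame(ce = 1:6, cp = exp(1:6))
  expect_equal(spearman_correlation(up)$r, 1)
  down <- data.frame(ce = 1:6, cp = -(1:6))
  expect_equal(spearman_correlation(down)$r, -1)
  # frozen hand-ranked value for x=[1,2,2,3], y=[1,2,3,4]
  tied <- data.frame(ce = c(1, 2, 2, 3), cp = c(1, 2, 3, 4))
  expect_equal(spearman_correlation(tied)$r, 0.948683298051, tolerance = 1e-9)
  # matches the base implementation on random data
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_correlation(data.frame(ce = x, cp = y))
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_correlation(data.frame(ce = c(1, 1, 1), cp = 1:3)),
               class = "b2p_undefined_correlation")
})

test_that("fit_loglog recovers the generating line exactly when noiseless", {
  ce <- exp(seq(4, 10, length.out = 25))
  cp <- exp(1.42 * log(ce) - 1.70)
  m <- fit_loglog(data.frame(ce = ce, cp = cp))
  expect_equal(m$slope, 1.42, tolerance = 1e-9)
  expect_equal(m$intercept, -1.70, tolerance = 1e-9)
  expect_equal(m$r_squared, 1.0, tolerance = 1e-9)
  # identity line
  mi <- fit_loglog(data.frame(ce = c(1, 10, 100), cp = c(1, 10, 100)))
  expect_equal(mi$slope, 1, tolerance = 1e-9)
  expect_equal(mi$intercept, 0, tolerance = 1e-9)
})

test_that("fit_loglog slope is stable under 5% multiplicative noise", {
  set.seed(31)
  ce <- exp(runif(60, 4, 10))
  cp <- exp(1.42 * log(ce) - 1.70) * exp(rnorm(60, 0, 0.05))
  m <- fit_loglog(data.frame(ce = ce, cp = cp))
  expect_lt(abs(m$slope - 1.42), 0.1)
})

test_that("fit_loglog rejects invalid inputs", {
  expect_error(fit_loglog(data.frame(ce = c(1, 2), cp = c(1, 2))),
               class = "b2p_regression_error")
  expect_error(fit_loglog(data.frame(ce = c(1, -2, 3), cp = c(1, 2, 3))),
               class = "b2p_regression_error")
  expect_error(fit_loglog(data.frame(ce = c(2, 2, 2), cp = c(1, 2, 3))),
               class = "b2p_regression_error")
})

test_that("predict_plasma applies the power law and round-trips the fit", {
  printed <- structure(list(slope = 1.42, intercept = -1.70,
                            r_squared = NA, n_pairs = NA,
                            ce_unit = "pptv", cp_unit = "ng/mL"),
                       class = "loglog_model")
  expect_equal(predict_plasma(printed, 5870), 41036.0437854, tolerance = 1e-6)
  ident <- structure(list(slope = 1, intercept = 0), class = "loglog_model")
  expect_equal(predict_plasma(ident, 123.4), 123.4)
  expect_true(predict_plasma(printed, 6000) > predict_plasma(printed, 5000))
  expect_error(predict_plasma(printed, -1), class = "b2p_domain_error")
  # fit-then-predict on self-generated data reproduces inputs exactly
  ce <- exp(seq(5, 9, length.out = 10))
  cp <- exp(1.1 * log(ce) + 0.3)
  m <- fit_loglog(data.frame(ce = ce, cp = cp))
  expect_equal(predict_plasma(m, ce), cp, tolerance = 1e-9)
})

test_that("icc_agreement matches the aov mean-squares oracle", {
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:10, 1)
    a <- rnorm(n, 10, 3)
    p <- a + rnorm(n, 0.5, 1)
    got <- icc_agreement(a, p)
    expect_equal(got$icc, icc_oracle(a, p), tolerance = 1e-10)
    expect_true(got$icc <= 1)
    expect_true(got$loa_low <= got$bias && got$bias <= got$loa_high)
  }
})

test_that("icc_agreement degenerate and shifted cases", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- icc_agreement(x, x)
  expect_equal(perfect$icc, 1.0)
  expect_equal(perfect$bias, 0)
  expect_equal(c(perfect$loa_low, perfect$loa_high), c(0, 0))
  shifted <- icc_agreement(x, x + 2)
  expect_equal(shifted$bias, 2)
  expect_equal(shifted$loa_low, 2)   # sd of differences is 0
  expect_equal(shifted$loa_high, 2)
  expect_error(icc_agreement(rep(1, 4), rep(1, 4)), class = "b2p_undefined_icc")
})

test_that("adding noise strictly decreases expected ICC", {
  set.seed(77)
  x <- rnorm(40, 10, 3)
  icc_clean <- icc_agreement(x, x)$icc
  icc_noisy <- mean(replicate(20, icc_agreement(x, x + rnorm(40, 0, 2))$icc))
  expect_equal(icc_clean, 1)
  expect_lt(icc_noisy, 1)
})

test_that("one-way ANOVA reproduces the hand-computed F", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$statistic, 3.0)          # SSB = 6, SSW = 6 by hand
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, pf(3, 2, 6, lower.tail = FALSE))
  # identical group means -> F = 0
  expect_equal(one_way_anova(list(c(1, 3), c(2, 2), c(1, 3)))$statistic, 0)
  # matches stats::oneway.test with equal variances on random data
  set.seed(3)
  g <- list(rnorm(8), rnorm(8, 0.5), rnorm(8, 1))
  got <- one_way_anova(g)
  ref <- stats::oneway.test(v ~ f, data = data.frame(
    v = unlist(g), f = factor(rep(1:3, each = 8))), var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("compare_parameters pairs by subject and refuses V1/CL/AUC", {
  same <- compare_parameters(c(1, 2, 3), c(1, 2, 3), "K10")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diffs <- compare_parameters(c(2, 0), c(1, 1), "K21")  # paired diffs +1, -1
  expect_equal(diffs$statistic, 0)
  expect_error(compare_parameters(1:3, 4:6, "V1"),
               class = "b2p_refused_comparison")
  expect_error(compare_parameters(1:3, 4:6, "CL"),
               class = "b2p_refused_comparison")
  expect_error(compare_parameters(1:3, 4:6, "AUC_0_120"),
               class = "b2p_refused_comparison")
  # paired matches stats::t.test where defined
  set.seed(4)
  a <- rnorm(10); b <- a + rnorm(10, 0.3)
  got <- compare_parameters(a, b, "t_half_beta")
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # Welch option
  gw <- compare_parameters(a, b, "K12", paired = FALSE)
  rw <- t.test(a, b, paired = FALSE)
  expect_equal(gw$statistic, unname(rw$statistic), tolerance = 1e-12)
})
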