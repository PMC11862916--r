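# Compartmental core: micro/macro algebra, closed-form prediction vs the
# RK4 oracle, least-squares fitting, model selection, derived parameters.

test_that("micro_to_macro reproduces the two-compartment root algebra", {
  m <- micro_params(V1 = 0.21, K10 = 0.25, K12 = 0.13, K21 = 0.03)
  d <- dose_event(4.76)
  mac <- micro_to_macro(m, d)
  # frozen from the quadratic-root oracle (helper computation)
  expect_equal(mac$exponents, c(0.390809041761, 0.0191909582394), tolerance = 1e-9)
  expect_equal(mac$coefficients, c(22.0073743517, 0.659292314982), tolerance = 1e-9)
  # t = 0 mass identity
  expect_equal(sum(mac$coefficients), d$amount / m$V1, tolerance = 1e-12)
})

test_that("one-compartment macro constants are (dose/V1, K10)", {
  m <- micro_params(V1 = 0.5, K10 = 0.2)
  mac <- micro_to_macro(m, dose_event(10))
  expect_equal(mac$coefficients, 20)
  expect_equal(mac$exponents, 0.2)
  # tiny K12/K21 approaches the one-compartment limit
  m2 <- micro_params(V1 = 0.5, K10 = 0.2, K12 = 1e-8, K21 = 1e-8)
  mac2 <- micro_to_macro(m2, dose_event(10))
  expect_equal(max(mac2$coefficients), 20, tolerance = 1e-5)
  expect_equal(mac2$exponents[1], 0.2, tolerance = 1e-5)
})

test_that("micro <-> macro round trip is the identity (randomized)", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_micro2()
    d <- dose_event(stats::runif(1, 1, 10))
    back <- macro_to_micro(micro_to_macro(m, d), d)
    for (f in c("V1", "K10", "K12", "K21")) {
      expect_equal(back[[f]], m[[f]], tolerance = 1e-9)
    }
  }
})

test_that("macro_to_micro handles the monoexponential and rejects junk", {
  d <- dose_event(10)
  m <- macro_to_micro(macro_params(20, 0.3), d)
  expect_equal(m$n_compartments, 1L)
  expect_equal(m$K10, 0.3)
  expect_equal(m$V1, 0.5)
  expect_error(macro_to_micro(macro_params(c(-1, 2), c(0.5, 0.1)), d),
               class = "b2p_inconsistent_macro")
})

test_that("closed-form prediction matches the ODE oracle", {
  # printed-parameter case with frozen oracle values
  m <- micro_params(V1 = 0.21, K10 = 0.25, K12 = 0.13, K21 = 0.03)
  d <- dose_event(4.76)
  mac <- micro_to_macro(m, d)
  expect_equal(predict_concentration(mac, d, 0), 4.76 / 0.21, tolerance = 1e-12)
  expect_equal(predict_concentration(mac, d, 1), 15.534954547, tolerance = 1e-9)
  # randomized two- and three-compartment oracle equivalence
  set.seed(99)
  times <- c(0.5, 1, 2, 5, 10, 30, 60, 120)
  for (i in 1:10) {
    m2 <- random_micro2()
    d2 <- dose_event(stats::runif(1, 1, 10))
    closed <- predict_concentration(micro_to_macro(m2, d2), d2, times)
    ode <- ode_concentration(m2, d2$amount, times)
    expect_lt(max(abs(closed - ode) / ode), 1e-6)
  }
  m3 <- micro_params(V1 = 0.2, K10 = 0.2, K12 = 0.1, K21 = 0.05,
                     K13 = 0.06, K31 = 0.02)
  d3 <- dose_event(5)
  closed3 <- predict_concentration(micro_to_macro(m3, d3), d3, times)
  expect_lt(max(abs(closed3 - ode_concentration(m3, 5, times)) /
                  closed3), 1e-6)
})

test_that("bolus curves decay monotonically; infusion peaks at end of infusion", {
  mac <- macro_params(c(10, 2), c(0.5, 0.02))
  d <- dose_event(5)
  tt <- seq(0, 120, by = 0.5)
  cc <- predict_concentration(mac, d, tt)
  expect_true(all(diff(cc) < 0))
  # zero-order infusion: rises during infusion, decays after
  di <- dose_event(5, duration = 2)
  ci <- predict_concentration(mac, di, tt)
  expect_true(all(diff(ci[tt <= 2]) > 0))
  expect_true(all(diff(ci[tt >= 2]) < 0))
  # infusion converges to bolus as duration -> 0
  dshort <- dose_event(5, duration = 1e-6)
  expect_equal(predict_concentration(mac, dshort, c(1, 10, 60)),
               predict_concentration(mac, d, c(1, 10, 60)), tolerance = 1e-5)
})

test_that("noiseless fits recover printed parameter sets to <= 1%", {
  # plasma schedule, medium-dose plasma parameters
  s <- noiseless_series(BM_PLASMA, PLASMA_TIMES)
  fit <- fit_compartment_model(s, dose_event(BM_PLASMA$dose), 2)
  expect_lt(abs(fit$micro$K10 - 0.25) / 0.25, 0.01)
  expect_lt(abs(fit$micro$K12 - 0.13) / 0.13, 0.01)
  expect_lt(abs(fit$micro$K21 - 0.03) / 0.03, 0.01)
  expect_lt(abs(fit$micro$V1 - 0.21) / 0.21, 0.01)
  # 20-s breath grid, high-dose breath parameters
  sb <- noiseless_series(BH_BREATH, BREATH_TIMES, matrix = "breath")
  fitb <- fit_compartment_model(sb, dose_event(BH_BREATH$dose), 2)
  expect_lt(abs(fitb$micro$K21 - 0.10) / 0.10, 0.01)
  expect_lt(abs(fitb$micro$K10 - 0.11) / 0.11, 0.01)
})

test_that("noisy fits recover parameters with bounded median error", {
  set.seed(1234)
  errs <- replicate(40, {
    m <- random_micro2()
    d <- dose_event(5)
    v <- predict_concentration(micro_to_macro(m, d), d, PLASMA_TIMES)
    v <- v * exp(rnorm(length(v), 0, sqrt(log(1 + 0.05^2))))
    s <- concentration_series("n", "plasma", PLASMA_TIMES, v, "ug/mL")
    f <- fit_compartment_model(s, d, 2)
    abs(f$micro$K10 - m$K10) / m$K10
  })
  expect_lt(median(errs), 0.15)
})

test_that("monoexponential data give an ssr ~ 0 one-compartment fit", {
  d <- dose_event(8)
  v <- 16 * exp(-0.3 * PLASMA_TIMES)
  s <- concentration_series("m", "plasma", PLASMA_TIMES, v, "ug/mL")
  f <- fit_compartment_model(s, d, 1)
  expect_lt(f$ssr, 1e-10)
  expect_equal(f$micro$K10, 0.3, tolerance = 1e-4)
  expect_equal(f$micro$V1, 0.5, tolerance = 1e-4)
})

test_that("fitting refuses underdetermined series", {
  s <- concentration_series("u", "plasma", c(1, 3, 5), c(5, 4, 3), "ug/mL")
  expect_error(fit_compartment_model(s, dose_event(5), 2),
               class = "b2p_data_error")
})

test_that("select_model picks the generating structure by AIC", {
  # clearly biexponential data -> 2 compartments
  s2 <- noiseless_series(BM_PLASMA, PLASMA_TIMES)
  sel2 <- select_model(s2, dose_event(BM_PLASMA$dose))
  expect_equal(sel2$n_compartments, 2L)
  expect_equal(nrow(sel2$aic_table), 3L)
  expect_false(is.null(sel2$fit2))
  # monoexponential data -> 1 compartment
  v <- 16 * exp(-0.3 * PLASMA_TIMES)
  s1 <- concentration_series("m", "plasma", PLASMA_TIMES, v, "ug/mL")
  sel1 <- select_model(s1, dose_event(8))
  expect_equal(sel1$n_compartments, 1L)
})

test_that("derived parameters match closed forms and the trapezoid oracle", {
  s <- noiseless_series(BM_PLASMA, PLASMA_TIMES)
  fit <- fit_compartment_model(s, dose_event(BM_PLASMA$dose), 2)
  der <- derived_params(fit, T = 120)
  expect_equal(der$t_half_alpha, 1.77362114612, tolerance = 1e-3)
  expect_equal(der$t_half_beta, 36.1184247245, tolerance = 1e-3)
  expect_equal(der$auc_inf, 4.76 / (0.21 * 0.25), tolerance = 1e-3)
  expect_equal(der$auc_0_T, 87.2323678426, tolerance = 1e-3)
  # algebraic identity auc_inf == dose/(V1 K10) holds for the fit exactly
  expect_equal(der$auc_inf,
               fit$dose$amount / (fit$micro$V1 * fit$micro$K10),
               tolerance = 1e-9)
  # trapezoid oracle on a dense grid
  tt <- seq(0, 120, by = 0.01)
  cc <- predict_concentration(fit$macro, fit$dose, tt)
  expect_equal(der$auc_0_T, trapezoid_auc(tt, cc), tolerance = 1e-4)
})

test_that("auc_inf conservation holds for randomized parameter sets", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_micro2()
    d <- dose_event(stats::runif(1, 1, 10))
    mac <- micro_to_macro(m, d)
    expect_equal(sum(mac$coefficients / mac$exponents),
                 d$amount / (m$V1 * m$K10), tolerance = 1e-9)
  }
})

test_that("observed metrics honour the tie and grid rules", {
  s <- concentration_series("t", "plasma", c(1, 3, 5), c(5, 5, 2), "ug/mL")
  om <- observed_metrics(s)
  expect_equal(om$t_max, 1)       # earliest tie
  expect_equal(om$c_max, 5)
  # bolus plasma profiles sampled on the blood-draw schedule peak at 1 min
  s2 <- noiseless_series(BM_PLASMA, PLASMA_TIMES)
  expect_equal(observed_metrics(s2)$t_max, 1)
  # breath grid membership: t_max is a multiple of 1/3 min
  sb <- noiseless_series(BH_BREATH, BREATH_TIMES, matrix = "breath")
  tm <- observed_metrics(sb)$t_max
  expect_equal(tm %% (1 / 3), 0, tolerance = 1e-12)
  # all-censored series has no metrics
  s3 <- concentration_series("c", "breath", c(1, 2), c(0, 0), "ppbv",
                             censored = rep("below_lod_zeroed", 2))
  expect_error(observed_metrics(s3), class = "b2p_metrics_unavailable")
})
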