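# Calibration: quadratic fit, inversion with LOD flagging, units.

# the instrument's published curve: y = -2794 + 24481 x + 1427 x^2
PRINTED_CURVE <- calibration_curve(-2794, 24481, 1427,
                                   valid_range = c(0.04, 55.68))
STANDARD_LEVELS <- c(0.04, 0.5, 1, 5, 10, 25, 55.68)

test_that("fitting exact quadratic points recovers the coefficients", {
  std <- generate_calibration_standards(PRINTED_CURVE, STANDARD_LEVELS)
  curve <- fit_calibration(std)
  expect_lt(abs(curve$c1 - 24481) / 24481, 1e-3)
  expect_lt(abs(curve$c2 - 1427) / 1427, 1e-3)
  expect_equal(curve$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(curve$valid_range, c(0.04, 55.68))
})

test_that("a linear truth yields c2 ~ 0", {
  std <- data.frame(concentration_ppbv = c(1, 2, 5, 10, 20),
                    signal_intensity = 100 + 50 * c(1, 2, 5, 10, 20))
  curve <- fit_calibration(std)
  expect_equal(curve$c2, 0, tolerance = 1e-9)
  expect_equal(curve$c1, 50, tolerance = 1e-9)
})

test_that("fit_calibration enforces its preconditions", {
  expect_error(
    fit_calibration(data.frame(concentration_ppbv = c(1, 1, 2),
                               signal_intensity = c(1, 1, 2))),
    class = "b2p_calibration_error")
})

test_that("signal inversion returns the printed concentrations", {
  inv <- signal_to_concentration(PRINTED_CURVE, 23114)
  expect_equal(inv$concentration_ppbv, 1.0, tolerance = 1e-9)
  expect_false(inv$below_lod)
  expect_equal(signal_to_concentration(PRINTED_CURVE, 384716)$concentration_ppbv,
               10.0, tolerance = 1e-9)
  # signal equal to the intercept maps to x = 0, clamped + flagged
  at0 <- signal_to_concentration(PRINTED_CURVE, -2794)
  expect_equal(at0$concentration_ppbv, 0)
  expect_true(at0$below_lod)
  # below the intercept: clamped to zero
  neg <- signal_to_concentration(PRINTED_CURVE, -10000)
  expect_equal(neg$concentration_ppbv, 0)
  expect_true(neg$below_lod)
})

test_that("forward-then-inverse is the identity and monotone", {
  x <- seq(0.05, 55, length.out = 40)
  sig <- concentration_to_signal(PRINTED_CURVE, x)
  back <- signal_to_concentration(PRINTED_CURVE, sig)$concentration_ppbv
  expect_equal(back, x, tolerance = 1e-9)
  expect_true(all(diff(back) > 0))
})

test_that("extrapolation warns inside 10% and refuses beyond", {
  hi <- concentration_to_signal(PRINTED_CURVE, 58)   # < 10% past 55.68
  expect_warning(signal_to_concentration(PRINTED_CURVE, hi),
                 class = "b2p_extrapolation")
  far <- concentration_to_signal(PRINTED_CURVE, 70)
  expect_error(suppressWarnings(signal_to_concentration(PRINTED_CURVE, far)),
               class = "b2p_out_of_range")
})

test_that("blank-based LOD estimator follows the 3s/10s rule", {
  blanks <- c(-2794, -2794, -2794) + c(-50, 0, 50)
  est <- estimate_lod(PRINTED_CURVE, blanks)
  s <- sd(blanks)
  expect_equal(est$lod, 3 * s / 24481, tolerance = 1e-9)
  expect_equal(est$loq, 10 * s / 24481, tolerance = 1e-9)
  expect_lt(est$lod, est$loq)
})

test_that("unit conversions multiply by 1000 and round trip", {
  expect_equal(convert_units(5.87, "ppbv", "pptv"), 5870)
  expect_equal(convert_units(1, "ug/mL", "ng/mL"), 1000)
  expect_equal(convert_units(convert_units(3.2, "ppbv", "pptv"), "pptv", "ppbv"), 3.2)
  expect_error(convert_units(1, "ppbv", "ng/mL"), class = "b2p_unit_error")
})

test_that("calibration JSON round trips", {
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(PRINTED_CURVE, path)
  back <- read_calibration_json(path)
  expect_equal(back$c1, PRINTED_CURVE$c1)
  expect_equal(back$lod, PRINTED_CURVE$lod)
  expect_equal(back$valid_range, PRINTED_CURVE$valid_range)
})

test_that("noisy standards recover coefficients with bounded median error", {
  # With 5% multiplicative noise on 7 levels the quadratic term dominates
  # the high standards, so c1 is the weakly identified coefficient: the
  # median relative errors measured by direct simulation (200 seeds) are
  # ~15% for c1 and ~8% for c2. Assert medians over a fixed seed batch
  # stay below 20% / 10%.
  errs <- vapply(1:50, function(s) {
    std <- generate_calibration_standards(PRINTED_CURVE, STANDARD_LEVELS,
                                          noise_cv = 0.05, seed = s)
    curve <- fit_calibration(std)
    c(abs(curve$c1 - 24481) / 24481, abs(curve$c2 - 1427) / 1427)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.20)
  expect_lt(median(errs[2, ]), 0.10)
})
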