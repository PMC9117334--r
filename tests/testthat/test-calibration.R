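sat <- function(a1, a2, a3) calibration_fit("sat_exp", c(a1, a2, a3))
sig <- function(a1, a2, a3, a4) calibration_fit("sigmoid", c(a1, a2, a3, a4))

test_that("model evaluation follows the closed forms", {
  f <- sat(2, 0.5, 0.3)
  expect_equal(eval_model(f, 0), 0.3)
  expect_equal(eval_model(f, 1e6), 2.3, tolerance = 1e-9)
  expect_equal(eval_model(sig(1, 0.2, 1, 2), 1), 0.6)
  expect_equal(eval_model(sig(1, 0.2, 1, 2), 0), 1)
  expect_error(eval_model(f, -1), "non-negative")
  expect_error(calibration_fit("sat_exp", c(1, -1, 0)), "a2 > 0")
  expect_error(calibration_fit("sigmoid", c(1, 1, 1, 1)), "a1 != a2")
  expect_error(calibration_fit("sigmoid", c(1, 2, -1, 1)), "a3 > 0")
})

test_that("evaluation and inversion are exact mutual inverses", {
  x <- seq(0.2, 10, length.out = 60)
  fits <- list(sat(1.8, 0.35, 0.12), sig(0.9, 5.2, 0.14, 1.55),
               sig(1.2, 0.2, 0.5, 1.1))  # decreasing sigmoid too
  for (f in fits) {
    expect_lt(max(abs(x - invert_model(f, eval_model(f, x)))), 1e-9)
  }
  f11 <- sat(1, 1, 0)
  expect_equal(invert_model(f11, 1 - exp(-2)), 2, tolerance = 1e-12)
  expect_error(invert_model(f11, 1.5), "outside the invertible range")
  expect_error(invert_model(sig(1, 5, 1, 1), 5.2), "outside")
})

test_that("noiseless fits recover the generating coefficients", {
  x <- c(0.3, 0.6, 0.9, 1.4, 2.2, 3.5, 5.0, 7.5)
  true_sat <- c(a1 = 2.1, a2 = 0.42, a3 = 0.15)
  y <- true_sat[1] * (1 - exp(-true_sat[2] * x)) + true_sat[3]
  f <- fit_calibration(x, y, model = "sat_exp")
  expect_equal(unname(f$coefficients), unname(true_sat), tolerance = 1e-6)
  true_sig <- c(a1 = 1.0, a2 = 5.5, a3 = 0.12, a4 = 1.6)
  ys <- true_sig[2] + (true_sig[1] - true_sig[2]) / (1 + true_sig[3] * x^true_sig[4])
  g <- fit_calibration(x, ys, model = "sigmoid")
  expect_equal(unname(g$coefficients), unname(true_sig), tolerance = 1e-6)
  # weighted fit on exact data recovers the same optimum
  gw <- fit_calibration(x, ys, uncertainties = seq(0.01, 0.08, length.out = 8),
                        model = "sigmoid")
  expect_equal(unname(gw$coefficients), unname(true_sig), tolerance = 1e-6)
  # exactly determined: three points, zero residuals
  f3 <- fit_calibration(x[1:3], y[1:3], model = "sat_exp")
  expect_lt(max(abs(f3$residuals)), 1e-9)
  expect_error(fit_calibration(x[1:2], y[1:2], model = "sat_exp"),
               "at least 3")
})

test_that("dose calibration and quenched-dose inversion are consistent", {
  doses <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1)
  y <- 2.3 * (1 - exp(-0.5 * doses))
  fit <- calibrate_dose(y, doses)
  expect_equal(eval_model(fit, doses), y, tolerance = 1e-8)
  grid <- seq(0.1, 1.1, by = 0.05)
  expect_true(all(diff(eval_model(fit, grid)) > 0))
  expect_equal(estimate_quenched_dose(fit, y[4]), 0.7, tolerance = 1e-8)
  expect_true(all(diff(estimate_quenched_dose(fit, sort(y))) > 0))
  expect_warning(calibrate_dose(c(y, 2.2), c(doses, 2.5)), "span")
})

test_that("LET calibration model choice follows the correction flag", {
  tm <- truth_model()
  lets <- c(0.44, 0.8, 1.3, 2.1, 3.4, 5.0, 6.5)
  corr <- truth_ratio(tm, lets) / tm$ratio_beta
  fit <- calibrate_let(corr, lets, corrected = TRUE)
  expect_identical(fit$model, "sigmoid")
  truth_co <- c(tm$ratio_coef[1] / tm$ratio_beta,
                tm$ratio_coef[2] / tm$ratio_beta,
                tm$ratio_coef[3], tm$ratio_coef[4])
  expect_equal(unname(fit$coefficients), truth_co, tolerance = 1e-6)
  expect_equal(estimate_let(fit, corr[3]), lets[3], tolerance = 1e-8)
  grid <- seq(0.4, 10, length.out = 40)
  expect_true(all(diff(eval_model(fit, grid)) > 0))
  raw <- calibrate_let(truth_ratio(tm, lets), lets, corrected = FALSE)
  expect_identical(raw$model, "sat_exp")
  expect_error(calibrate_let(corr[1:3], c(1, 1.2, 1.5)), "factor 2")
  # removing a point changes the weighted fit (sensitivity smoke contract)
  w <- rep(0.01, length(lets))
  fit_all <- calibrate_let(corr, lets, w)
  fit_less <- calibrate_let(corr[-2], lets[-2], w[-2])
  expect_false(identical(fit_all$coefficients, fit_less$coefficients))
})

test_that("delta-method LET uncertainty matches a finite-difference oracle", {
  f <- sig(1.0, 5.5, 0.12, 1.6)
  r <- eval_model(f, 2.5)
  expect_equal(propagate_let_uncertainty(f, r, 0), 0)
  s1 <- propagate_let_uncertainty(f, r, 0.01)
  expect_equal(propagate_let_uncertainty(f, r, 0.02), 2 * s1,
               tolerance = 1e-12)
  oracle <- (invert_model(f, r + 0.01) - invert_model(f, r - 0.01)) / 2
  expect_equal(s1, oracle, tolerance = 0.05)
})

test_that("the efficiency curve is anchored at 1 and tracks the truth chain", {
  tm <- truth_model()
  lets <- c(0.44, seq(1.5, 6.5, length.out = 8))
  ratio <- truth_ratio(tm, lets) / tm$ratio_beta
  # oracle: noiseless quenched dose from inverting the exact dose response
  k <- tm$dose_rate
  eta_true <- truth_efficiency(tm, lets)
  d <- 1.0
  dq <- -log(1 - (1 - exp(-k * d)) * eta_true) / k
  eff <- build_efficiency(dq[-1], rep(d, 8), ratio[-1], ratio[1])
  expect_equal(efficiency_at(eff, ratio[1]), 1, tolerance = 1e-12)
  expect_equal(efficiency_at(eff, ratio[-1]), dq[-1] / d, tolerance = 1e-3)
  expect_true(all(diff(efficiency_at(eff, seq(1.2, 4.5, by = 0.1))) < 0))
  # a measured 0.8 Gy at 1.0 Gy delivered enters as an efficiency point 0.8
  eff2 <- build_efficiency(c(0.95, 0.87, 0.8), c(1.0, 1.0, 1.0),
                           c(1.6, 2.2, 3.0), 1.2)
  expect_equal(eff2$points$eta[3], 0.8)
  expect_warning(
    build_efficiency(c(0.7, 0.95, 0.85), c(1, 1, 1), c(2, 3, 3.5), 1.1),
    "non-monotone"
  )
})

test_that("quenching correction scales by the inverse efficiency", {
  expect_equal(correct_dose(0.8, 1), 0.8)
  expect_equal(correct_dose(0.8, 0.8), 1.0)
  expect_error(correct_dose(1, 0), "positive")
  expect_error(correct_dose(1, 1.2), "bound")
})

test_that("calibration fits round-trip through JSON", {
  x <- c(0.3, 0.6, 0.9, 1.4, 2.2, 3.5, 5.0, 7.5)
  y <- 2.1 * (1 - exp(-0.42 * x)) + 0.15 + c(0.01, -0.01, 0, 0.02, 0, 0, -0.01, 0)
  f <- fit_calibration(x, y, model = "sat_exp")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(f, path, created_from = "unit test")
  g <- read_calibration(path)
  expect_equal(g$coefficients, f$coefficients, tolerance = 1e-12)
  expect_identical(g$model, f$model)
  expect_equal(g$x_range, f$x_range)
})
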