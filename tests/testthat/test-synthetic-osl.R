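test_that("detector sensitivities reproduce the configured CV and correlation", {
  tm <- truth_model()
  det0 <- sample_detector(tm, cv = 0)
  expect_identical(c(det0$s_blue, det0$s_uv), c(1, 1))
  set.seed(11)
  draws <- replicate(1e4, {
    d <- sample_detector(tm)
    c(d$s_blue, d$s_uv)
  })
  cv_obs <- apply(draws, 1, function(v) stats::sd(v) / mean(v))
  expect_equal(mean(cv_obs), 0.10, tolerance = 0.05)
  expect_true(all(abs(cv_obs - 0.10) < 0.005))
  expect_equal(stats::cor(log(draws[1, ]), log(draws[2, ])), 0.5,
               tolerance = 0.06)
  expect_true(all(draws > 0))
  expect_error(sample_detector(tm, cv = -1), "cv")
})

test_that("truth curves satisfy the model invariants", {
  tm <- truth_model()
  l <- seq(0.4, 10, length.out = 50)
  expect_true(all(diff(truth_ratio(tm, l)) > 0))
  expect_true(all(diff(truth_efficiency(tm, l)) < 0))
  expect_equal(truth_efficiency(tm, 0.44), 1, tolerance = 1e-12)
  # ratio spans roughly a factor 3-5 over the calibrated LET range
  span <- truth_ratio(tm, 6.5) / truth_ratio(tm, 0.4)
  expect_gt(span, 3)
  expect_lt(span, 5)
  # total emission (UV + in-gate blue) is LET-independent
  tot <- truth_efficiency(tm, l) * (truth_ratio(tm, l) + 0.5)
  expect_lt(max(tot) / min(tot) - 1, 0.05)
})

test_that("proton exposure composes sensitivity, dose response and quenching", {
  tm <- truth_model()
  det <- sample_detector(tm, cv = 0)
  ex <- expose(det, 1, tm$let_cal, tm)
  # at the calibration LET the efficiency factor is 1
  n0 <- tm$counts_per_gy / tm$dose_rate
  g1 <- (1 - exp(-tm$dose_rate)) * (1 + tm$gamma_blue * (1 - exp(-1 / tm$d0)))
  expect_equal(ex$blue, n0 * g1, tolerance = 1e-12)
  # doubling both sensitivities doubles the bands, leaves U/B unchanged
  det2 <- det
  det2$s_blue <- 2
  det2$s_uv <- 2
  ex2 <- expose(det2, 1, tm$let_cal, tm)
  expect_equal(ex2$blue / ex$blue, 2, tolerance = 1e-12)
  expect_equal(ex2$uv / ex2$blue, ex$uv / ex$blue, tolerance = 1e-12)
  expect_equal(expose(det, 0, 2, tm)$blue, 0)
  expect_error(expose(det, -1, 2, tm), "non-negative")
  expect_length(ex$detector$history, 1L)
})

test_that("reference exposure is sensitized by the prior proton dose", {
  tm0 <- truth_model(gamma_blue = 0, gamma_uv = 0)
  det <- sample_detector(tm0, cv = 0)
  fresh <- reference_expose(det, tm0)
  after <- reference_expose(expose(det, 1, 2, tm0)$detector, tm0)
  expect_equal(fresh$blue, after$blue, tolerance = 1e-12)
  # equal sensitivities and history -> identical reference
  tm <- truth_model()
  d1 <- expose(sample_detector(tm, cv = 0), 0.8, 3, tm)$detector
  d2 <- expose(sample_detector(tm, cv = 0), 0.8, 3, tm)$detector
  expect_equal(reference_expose(d1, tm)$uv, reference_expose(d2, tm)$uv)
  # sensitization grows monotonically with the prior dose
  m <- vapply(c(0, 0.3, 0.7, 1.1), function(d) {
    reference_expose(expose(sample_detector(tm, cv = 0), d, 2, tm)$detector,
                     tm)$blue
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("noiseless readout processing recovers the latent intensities up to the closed-form factor", {
  tm <- truth_model(dark_rate = 0)
  det <- sample_detector(tm, cv = 0)
  ex <- expose(det, 1, 2, tm)
  cur <- readout_curve(ex, tm, noise = FALSE)
  expect_length(cur$on, 100L)
  sig <- band_signals(cur)
  # processing factor: depletion truncation plus the last-10-channel
  # background over-subtraction (the tail of exp(-t/50) is not yet dark)
  tail10 <- exp(-270 / tm$tau_dep) - exp(-300 / tm$tau_dep)
  fac <- (1 - exp(-300 / tm$tau_dep)) - 10 * tail10
  expect_equal(sig$s_uv, ex$uv * fac, tolerance = 1e-10)
  expect_equal(sig$s_blue, ex$blue / 2 * fac, tolerance = 1e-10)
  expect_gt(fac, 0.97)
  # the factor is band-independent, so the measured UV/blue ratio is exact
  expect_equal(sig$s_uv / (2 * sig$s_blue), ex$uv / ex$blue,
               tolerance = 1e-10)
  # channel sums obey the depletion closed form
  expect_equal(sum(cur$on + cur$off),
               (ex$uv + ex$blue) * (1 - exp(-300 / tm$tau_dep)),
               tolerance = 1e-12)
  # zero latent signal -> zero net signal
  nul <- band_signals(readout_curve(list(blue = 0, uv = 0), tm,
                                    noise = FALSE))
  expect_equal(nul$s_blue, 0)
  expect_equal(nul$s_uv, 0)
})

test_that("a seeded study is reproducible with the designed structure", {
  tab <- sp_table()
  tm <- truth_model()
  fields <- list(
    proton_field("d1", 230, depths_pmma = 2,
                 cal_doses = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.1), table = tab),
    proton_field("f1", 70, depths_pmma = c(1.0, 2.0), table = tab)
  )
  ds1 <- generate_study(fields, tm, seed = 5)
  ds2 <- generate_study(fields, tm, seed = 5)
  expect_identical(ds1$packages, ds2$packages)
  expect_identical(ds1$readouts, ds2$readouts)
  expect_true(all(vapply(ds1$readouts, length, integer(1)) == 5L))
  cal <- ds1$packages[ds1$packages$field == "d1", ]
  expect_gte(nrow(cal), 6L)
  expect_equal(range(cal$true_dose), c(0.1, 1.1))
  expect_error(
    suppressWarnings(
      generate_study(list(proton_field("x", 70, depths_pmma = 4.5,
                                       table = tab)), tm, seed = 1)
    ),
    "beyond"
  )
})

test_that("the corrected ratio cancels detector sensitivity exactly", {
  tm <- truth_model()
  set.seed(3)
  ratio_of <- function(det) {
    ex <- expose(det, 0.7, 3.1, tm)
    ref <- reference_expose(ex$detector, tm)
    sig <- band_signals(readout_curve(ex, tm, noise = FALSE))
    rsig <- band_signals(readout_curve(ref, tm, noise = FALSE))
    uv_blue_ratio(sig, rsig)
  }
  r1 <- ratio_of(sample_detector(tm))
  r2 <- ratio_of(sample_detector(tm))
  expect_equal(r1$corrected, r2$corrected, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(r1$raw, r2$raw, tolerance = 1e-3)))
})

test_that("channel tables round-trip through CSV", {
  tab <- sp_table()
  tm <- truth_model()
  ds <- generate_study(
    list(proton_field("f1", 70, depths_pmma = 1.5, table = tab)),
    tm, seed = 2
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_posl_channels(ds, path)
  back <- read_posl_channels(path)
  expect_equal(back$P01[[1]]$proton$on, ds$readouts$P01[[1]]$proton$on)
  expect_equal(back$P01[[3]]$reference$off,
               ds$readouts$P01[[3]]$reference$off)
})
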