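test_that("entrance LET of a single layer approaches S(E0)", {
  tab <- sp_table()
  f <- proton_field("e", 230, depths_pmma = 0.01, table = tab)
  let0 <- fluence_let_profile(f)$fluence_let_kev_um
  expect_equal(let0, stopping_power(tab, 230) * 0.1, tolerance = 3e-3)
})

test_that("single-layer f-LET increases monotonically with depth", {
  tab <- sp_table()
  f <- proton_field("m", 70, table = tab)
  z <- seq(0.2, 3.4, by = 0.1)  # PMMA, up to just before the distal edge
  lets <- fluence_let_profile(f, z)$fluence_let_kev_um
  expect_true(all(diff(lets) > 0))
})

test_that("quadrature f-LET agrees with a brute-force range-sampling oracle", {
  tab <- sp_table()
  set.seed(42)
  e0 <- 100
  z <- 5            # cm water
  r0 <- csda_range(tab, e0)
  sig <- sqrt((0.012 * r0^0.935)^2 +
                (0.008 * e0 / stopping_power(tab, e0))^2)
  rp <- stats::rnorm(1e5, r0, sig)
  rp <- rp[rp > z]
  eg <- exp(seq(log(1), log(e0), length.out = 3000))
  rg <- csda_range(tab, eg)
  eres <- stats::approx(rg, eg, pmax(rp - z, min(rg)), rule = 2)$y
  mc <- mean(stopping_power(tab, eres)) * 0.1
  f <- proton_field("o", e0, table = tab)
  quad <- fluence_let_profile(f, z / 1.16)$fluence_let_kev_um
  expect_equal(quad, mc, tolerance = 0.01)
})

test_that("dose-averaged LET dominates the fluence average", {
  tab <- sp_table()
  f <- proton_field("d", 70, table = tab)
  prof <- fluence_let_profile(f, c(0.5, 1.5, 2.5, 3.2))
  expect_true(all(prof$dose_let_kev_um >= prof$fluence_let_kev_um))
  # narrow spectrum far from the peak: the two averages nearly coincide
  f2 <- proton_field("n", 230, depths_pmma = 2.0, table = tab)
  p2 <- fluence_let_profile(f2)
  expect_equal(p2$dose_let_kev_um, p2$fluence_let_kev_um, tolerance = 0.02)
})

test_that("70 MeV Bragg peak sits at the straggled CSDA range", {
  tab <- sp_table()
  f <- proton_field("p", 70, plateau_dose = 1, table = tab)
  z <- seq(3.0, 3.6, by = 0.005)  # PMMA
  prof <- depth_dose(f, z, normalize = "peak")
  z_peak_wet <- pmma_to_wet(z[which.max(prof$dose)])
  expect_gt(z_peak_wet, 3.9)
  expect_lt(z_peak_wet, 4.1)
  # entrance dose below the peak; nothing beyond range + straggling
  expect_lt(depth_dose(f, 0.2, normalize = "peak")$dose, max(prof$dose))
  # beyond range plus straggling (> R + 5 sigma) no proton arrives
  far <- suppressWarnings(depth_dose(f, 3.92, normalize = "peak")$dose)
  expect_equal(far, 0)
})

test_that("SOBP weights give a flat plateau and behave under rescaling", {
  tab <- sp_table()
  expect_equal(sobp_weights(100, c(4, 6), table = tab), 1)
  f <- f2_field()
  expect_true(all(f$weights >= 0))
  expect_equal(max(f$weights), 1)
  span <- c(f$distal - f$sobp_width, f$distal - 0.15)
  z <- seq(span[1], span[2], by = 0.1) / f$rsp  # 1 mm grid, PMMA
  dose <- depth_dose(f, z, normalize = "none")$dose
  expect_lt(max(dose) / min(dose) - 1, 0.02)
  # profiles invariant under uniform weight rescaling
  f3 <- proton_field("s", f$energies, weights = 3 * f$weights, table = tab)
  p1 <- fluence_let_profile(f, c(3, 5, 7))
  p3 <- fluence_let_profile(f3, c(3, 5, 7))
  expect_equal(p1$fluence_let_kev_um, p3$fluence_let_kev_um,
               tolerance = 1e-12)
  expect_equal(p3$dose / p1$dose, rep(3, 3), tolerance = 1e-12)
})

test_that("shift sensitivity is zero at zero shift and ranked by gradient", {
  f <- f2_field()
  zmid <- mid_plateau_depth(f)
  expect_equal(shift_sensitivity(f, zmid, 0), 0)
  distal <- (f$distal - 0.05) / f$rsp
  expect_gt(shift_sensitivity(f, distal, 0.5),
            shift_sensitivity(f, zmid, 0.5))
})

test_that("depths without fluence give flagged undefined LET", {
  tab <- sp_table()
  f <- proton_field("z", 70, table = tab)
  expect_warning(prof <- fluence_let_profile(f, 4.5), "undefined")
  expect_true(is.na(prof$fluence_let_kev_um))
  expect_error(proton_field("bad", 30, table = tab), "60")
  expect_error(proton_field("bad", 230, weights = 0, table = tab),
               "not all zero")
})
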