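# Synthetic Al2O3:C pulsed-OSL data: a ground-truth forward model of the
# blue (F-center) and UV (F+-center) emission bands versus dose and LET,
# detector-to-detector sensitivity variability, the built-in beta reference
# irradiation, and the pulsed readout with Poisson counting noise.

#' Ground-truth forward model of the synthetic detector population
#'
#' Holds every parameter of the synthetic data generator. The constructions
#' are chosen so the downstream empirical calibration forms hold exactly in
#' the noiseless limit:
#'
#' * the UV/blue ratio curve `r(LET)` is an increasing, saturating sigmoid
#'   `a2 + (a1 - a2) / (1 + a3 * LET^a4)`;
#' * the relative luminescence efficiency of both bands is
#'   `eta(LET) = (r(let_cal) + 1/2) / (r(LET) + 1/2)`, monotone decreasing
#'   with `eta(let_cal) = 1` and making the total emission during
#'   stimulation (UV plus the in-gate half of the blue band)
#'   LET-independent;
#' * the intrinsic dose response is
#'   `g(D) = (1 - exp(-k D)) * m(D)` with the sensitization factor
#'   `m(D) = 1 + gamma (1 - exp(-D / d0))` folded in, so that the
#'   reference-corrected dose response `g(D) eta / (g(D_ref) m(D))` is
#'   exactly a saturating exponential in dose.
#'
#' @param counts_per_gy Expected blue-band counts per Gy in the linear
#'   regime (Poisson noise ~0.1-0.3% per readout at the study doses).
#' @param dose_rate Saturation rate k of the dose response, 1/Gy.
#' @param gamma_blue,gamma_uv Sensitization amplitudes of the beta
#'   reference signal by the prior proton irradiation (equal by default so
#'   the sensitization cancels exactly from the corrected UV/blue ratio).
#' @param d0 Sensitization dose constant, Gy.
#' @param ratio_coef Coefficients `c(a1, a2, a3, a4)` of the truth UV/blue
#'   ratio sigmoid (a2 > a1 > 0, a3 > 0, a4 > 0: increasing from a1 to a2).
#' @param ratio_beta Latent UV/blue ratio of the beta reference readout
#'   (the beta source is treated as unquenched, low-LET-like).
#' @param let_cal Calibration LET in keV/um at which the efficiency is 1
#'   (the 230 MeV / 2 cm PMMA condition).
#' @param cv Per-band inter-detector sensitivity coefficient of variation.
#' @param rho Log-scale correlation of the blue and UV sensitivities.
#' @param dark_rate Dark background, counts per 3 s channel per gate.
#' @param tau_dep Stimulation depletion time constant, s.
#' @param ref_dose Beta reference dose, Gy (30 s at 0.0467 Gy/s).
#' @param n_channels,channel_width Readout binning: 100 channels of 3 s.
#' @return An object of class `"truth_model"`.
#' @export
truth_model <- function(counts_per_gy = 1e6,
                        dose_rate = 0.5,
                        gamma_blue = 0.25,
                        gamma_uv = 0.25,
                        d0 = 1.5,
                        ratio_coef = c(0.10, 0.55, 0.12, 1.6),
                        ratio_beta = 0.10,
                        let_cal = 0.44,
                        cv = 0.10,
                        rho = 0.5,
                        dark_rate = 20,
                        tau_dep = 50,
                        ref_dose = 1.4,
                        n_channels = 100L,
                        channel_width = 3) {
  stopifnot(cv >= 0, rho > -1, rho < 1, tau_dep > 0, ratio_beta > 0)
  a <- ratio_coef
  if (!(a[2L] > a[1L] && a[1L] > 0 && a[3L] > 0 && a[4L] > 0)) {
    stop("ratio_coef must satisfy a2 > a1 > 0, a3 > 0, a4 > 0")
  }
  tm <- structure(
    list(
      counts_per_gy = counts_per_gy, dose_rate = dose_rate,
      gamma_blue = gamma_blue, gamma_uv = gamma_uv, d0 = d0,
      ratio_coef = a, ratio_beta = ratio_beta, let_cal = let_cal,
      cv = cv, rho = rho, dark_rate = dark_rate, tau_dep = tau_dep,
      ref_dose = ref_dose, ref_time = 30, ref_dose_rate = ref_dose / 30,
      n_channels = as.integer(n_channels), channel_width = channel_width
    ),
    class = "truth_model"
  )
  stopifnot(abs(truth_efficiency(tm, let_cal) - 1) < 1e-12)
  tm
}

#' @export
print.truth_model <- function(x, ...) {
  cat(sprintf(
    "<truth_model> CV %.0f%%, rho %.2f, %.0g blue counts/Gy, ref %.2g Gy\n",
    100 * x$cv, x$rho, x$counts_per_gy, x$ref_dose
  ))
  invisible(x)
}

#' Truth UV/blue ratio at a given LET
#' @param truth A [truth_model()].
#' @param let LET in keV/um.
#' @return Latent UV/blue intensity ratio.
#' @export
truth_ratio <- function(truth, let) {
  a <- truth$ratio_coef
  a[2L] + (a[1L] - a[2L]) / (1 + a[3L] * let^a[4L])
}

#' Truth relative luminescence efficiency at a given LET
#' @inheritParams truth_ratio
#' @return Efficiency, 1 at `truth$let_cal` and decreasing with LET.
#' @export
truth_efficiency <- function(truth, let) {
  (truth_ratio(truth, truth$let_cal) + 0.5) / (truth_ratio(truth, let) + 0.5)
}

# intrinsic dose response (dimensionless, ~ k*D at low dose)
truth_dose_response <- function(truth, dose) {
  (1 - exp(-truth$dose_rate * dose)) * sensitization(truth, dose, "blue")
}

# reference-sensitization multiplier m(D_prior)
sensitization <- function(truth, dose_prior, band = c("blue", "uv")) {
  band <- match.arg(band)
  g <- if (band == "blue") truth$gamma_blue else truth$gamma_uv
  1 + g * (1 - exp(-dose_prior / truth$d0))
}

#' Draw a detector from the population
#'
#' Per-band sensitivity factors are drawn from a correlated bivariate
#' lognormal with unit mean, the configured per-band CV and log-scale
#' correlation `rho`. Uses the current RNG state (seed it with
#' [set.seed()] or via [generate_study()]).
#'
#' @param truth A [truth_model()].
#' @param id Detector identifier.
#' @param cv,rho Override the population CV / correlation.
#' @return An object of class `"osl_detector"`.
#' @export
sample_detector <- function(truth, id = "osld", cv = truth$cv,
                            rho = truth$rho) {
  stopifnot(cv >= 0, rho > -1, rho < 1)
  if (cv == 0) {
    s <- c(1, 1)
  } else {
    sl <- sqrt(log(1 + cv^2))
    z <- stats::rnorm(2L)
    z2 <- c(z[1L], rho * z[1L] + sqrt(1 - rho^2) * z[2L])
    s <- exp(sl * z2 - sl^2 / 2)
  }
  structure(
    list(id = id, s_blue = s[1L], s_uv = s[2L], history = list()),
    class = "osl_detector"
  )
}

#' Expose a detector to a proton field
#'
#' Latent band intensities:
#' blue `B = s_blue * N * g(D) * eta(LET)` and
#' UV `U = s_uv * N * g(D) * eta(LET) * r(LET)`, where `N` converts to
#' expected counts. The irradiation is appended to the detector's history.
#'
#' @param detector An [sample_detector()] result.
#' @param dose Dose in Gy (>= 0).
#' @param let Fluence-averaged LET in water, keV/um.
#' @param truth A [truth_model()].
#' @return List with elements `detector` (updated), `blue`, `uv` (latent
#'   expected counts).
#' @export
expose <- function(detector, dose, let, truth) {
  stopifnot(inherits(detector, "osl_detector"))
  if (dose < 0) stop("dose must be non-negative")
  n0 <- truth$counts_per_gy / truth$dose_rate
  base <- n0 * truth_dose_response(truth, dose) * truth_efficiency(truth, let)
  detector$history <- c(
    detector$history,
    list(list(dose = dose, let = let, kind = "proton"))
  )
  list(
    detector = detector,
    blue = detector$s_blue * base,
    uv = detector$s_uv * base * truth_ratio(truth, let)
  )
}

#' Beta reference exposure of a detector
#'
#' The built-in beta source delivers `truth$ref_dose` unquenched
#' (efficiency 1, latent UV/blue ratio `ratio_beta`). The reference signal
#' is sensitized by the preceding proton irradiation through
#' `m_band = 1 + gamma_band (1 - exp(-D_prior / d0))`; with no prior proton
#' record the reference is unsensitized.
#'
#' @inheritParams expose
#' @return List with `detector`, `blue`, `uv` latent reference intensities.
#' @export
reference_expose <- function(detector, truth) {
  stopifnot(inherits(detector, "osl_detector"))
  protons <- Filter(function(h) h$kind == "proton", detector$history)
  d_prior <- if (length(protons)) protons[[length(protons)]]$dose else 0
  n0 <- truth$counts_per_gy / truth$dose_rate
  base <- n0 * truth_dose_response(truth, truth$ref_dose)
  detector$history <- c(
    detector$history,
    list(list(dose = truth$ref_dose, let = NA_real_, kind = "beta"))
  )
  list(
    detector = detector,
    blue = detector$s_blue * base * sensitization(truth, d_prior, "blue"),
    uv = detector$s_uv * base * sensitization(truth, d_prior, "uv") *
      truth$ratio_beta
  )
}

#' Pulsed-OSL readout of latent band intensities
#'
#' The latent counts are distributed over the channels by exponential
#' stimulation depletion `exp(-t / tau_dep)` (the fraction beyond the 300 s
#' readout, ~0.25% at the default time constant, is lost). The slow blue
#' band (35 ms lifetime, much longer than the 100 us pulse period) splits
#' its counts equally between the on and off gates of each channel; the
#' fast UV band (< 7 ns) is counted entirely in the on gates. A constant
#' dark rate is added to both gates, and each channel count is drawn from
#' a Poisson law around its expectation (unless `noise = FALSE`).
#'
#' @param latent List with `blue` and `uv` latent expected counts.
#' @param truth A [truth_model()].
#' @param noise Draw Poisson counts (`TRUE`) or return expectations.
#' @return A [posl_curve()].
#' @export
readout_curve <- function(latent, truth, noise = TRUE) {
  stopifnot(latent$blue >= 0, latent$uv >= 0)
  nc <- truth$n_channels
  edges <- seq(0, nc) * truth$channel_width
  frac <- exp(-edges[-(nc + 1L)] / truth$tau_dep) -
    exp(-edges[-1L] / truth$tau_dep)
  on <- latent$uv * frac + latent$blue * frac / 2 + truth$dark_rate
  off <- latent$blue * frac / 2 + truth$dark_rate
  if (noise) {
    on <- stats::rpois(nc, on)
    off <- stats::rpois(nc, off)
  }
  posl_curve(on, off, channel_width = truth$channel_width)
}

#' Generate a complete synthetic irradiation study
#'
#' For every OSLD position of every field, a package of five detectors is
#' drawn, proton-exposed with the beam model's dose and fluence-averaged
#' LET at that depth, then reference-irradiated, and both pulsed readouts
#' are simulated. A field with `cal_doses` (the 230 MeV dose-calibration
#' field) instead contributes one package per calibration dose at its
#' single depth. Seeded runs are bit-reproducible.
#'
#' @param fields List of [proton_field()] objects.
#' @param truth A [truth_model()].
#' @param seed Integer RNG seed.
#' @param noise Poisson counting noise on the readouts.
#' @param cv Override the inter-detector sensitivity CV.
#' @param n_per_package Detectors per package (5).
#' @return An object of class `"synthetic_dataset"`: a list with `packages`
#'   (data frame of per-package truth: field, depth, delivered dose, true
#'   f-LET), `readouts` (per package: per detector, `proton` and
#'   `reference` curves), and the `truth` model.
#' @export
generate_study <- function(fields, truth, seed = 1L, noise = TRUE,
                           cv = truth$cv, n_per_package = 5L) {
  set.seed(seed)
  meta <- list()
  readouts <- list()
  pkg_id <- 0L
  for (field in fields) {
    stopifnot(inherits(field, "proton_field"))
    if (!is.null(field$cal_doses)) {
      depths <- rep(field$depths_pmma[1L], length(field$cal_doses))
      doses <- field$cal_doses
    } else {
      depths <- field$depths_pmma
      doses <- depth_dose(field, depths)$dose
    }
    prof <- fluence_let_profile(field, depths)
    if (any(!is.finite(prof$fluence_let_kev_um))) {
      stop(sprintf("field %s: a depth lies beyond the beam range", field$name))
    }
    for (i in seq_along(depths)) {
      pkg_id <- pkg_id + 1L
      id <- sprintf("P%02d", pkg_id)
      meta[[pkg_id]] <- data.frame(
        package_id = id, field = field$name, depth_pmma = depths[i],
        true_dose = doses[i], true_let = prof$fluence_let_kev_um[i],
        stringsAsFactors = FALSE
      )
      members <- vector("list", n_per_package)
      for (j in seq_len(n_per_package)) {
        det <- sample_detector(truth, sprintf("%s-%d", id, j), cv = cv)
        ex <- expose(det, doses[i], prof$fluence_let_kev_um[i], truth)
        ref <- reference_expose(ex$detector, truth)
        members[[j]] <- list(
          detector_id = det$id,
          proton = readout_curve(ex, truth, noise = noise),
          reference = readout_curve(ref, truth, noise = noise)
        )
      }
      readouts[[id]] <- members
    }
  }
  structure(
    list(
      packages = do.call(rbind, meta), readouts = readouts, truth = truth,
      seed = seed, noise = noise
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d packages x %d detectors (seed %d, noise %s)\n",
    nrow(x$packages), length(x$readouts[[1L]]), x$seed, x$noise
  ))
  invisible(x)
}

#' Write the channel table of a synthetic dataset to CSV
#'
#' One row per channel and gate pair:
#' `package_id, detector_id, exposure_kind, channel_index, on_counts,
#' off_counts`.
#'
#' @param dataset A [generate_study()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_posl_channels <- function(dataset, path) {
  rows <- list()
  for (pid in names(dataset$readouts)) {
    for (m in dataset$readouts[[pid]]) {
      for (kind in c("proton", "reference")) {
        cur <- m[[kind]]
        rows[[length(rows) + 1L]] <- data.frame(
          package_id = pid, detector_id = m$detector_id,
          exposure_kind = kind,
          channel_index = seq_along(cur$on),
          on_counts = cur$on, off_counts = cur$off,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a channel table written by [write_posl_channels()]
#'
#' @param path CSV path.
#' @param channel_width Channel width in seconds.
#' @return A list of packages, each a list of members with `proton` and
#'   `reference` [posl_curve()] objects.
#' @export
read_posl_channels <- function(path, channel_width = 3) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (pid in unique(tab$package_id)) {
    sub <- tab[tab$package_id == pid, ]
    members <- list()
    for (did in unique(sub$detector_id)) {
      dsub <- sub[sub$detector_id == did, ]
      member <- list(detector_id = did)
      for (kind in c("proton", "reference")) {
        k <- dsub[dsub$exposure_kind == kind, ]
        k <- k[order(k$channel_index), ]
        member[[kind]] <- posl_curve(k$on_counts, k$off_counts,
                                     channel_width = channel_width)
      }
      members[[length(members) + 1L]] <- member
    }
    out[[pid]] <- members
  }
  out
}
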