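# Analytical proton pencil-beam model: pristine Bragg peaks and SOBPs with
# Gaussian range straggling, depth dose and fluence-/dose-averaged LET in
# water. Depths are specified in cm of PMMA and converted internally.

# total range spread: range straggling plus initial energy spread mapped
# through dR/dE = 1/S(E0)
range_sigma <- function(table, energy, energy_spread_frac) {
  r0 <- csda_range(table, energy)
  s_straggle <- 0.012 * r0^0.935
  s_energy <- energy_spread_frac * energy / stopping_power(table, energy)
  sqrt(s_straggle^2 + s_energy^2)
}

#' Define a proton field
#'
#' A field is a set of weighted energy layers plus the irradiation geometry:
#' OSLD measurement depths in PMMA, an optional SOBP plateau width and the
#' nominal dose delivered at the plateau (or, for a single layer, at the
#' Bragg peak). If `weights` is `NULL` and the field has several layers and
#' an SOBP width, layer weights are fitted with [sobp_weights()] so the
#' summed depth dose is flat over the distal `sobp_width` cm of water.
#'
#' @param name Field label.
#' @param energies Nominal layer energies in MeV (each within 60-250).
#' @param weights Relative layer weights (non-negative, not all zero), or
#'   `NULL` to fit SOBP weights.
#' @param depths_pmma OSLD measurement depths in cm PMMA.
#' @param sobp_width SOBP plateau width in cm of water, or `NULL` for a
#'   single-layer field.
#' @param plateau_dose Nominal dose (Gy) at the plateau (SOBP) or peak
#'   (single layer).
#' @param cal_doses Optional vector of doses (Gy) for a dose-calibration
#'   series delivered at a single depth (the first element of
#'   `depths_pmma`).
#' @param rsp Relative stopping power of PMMA, see [pmma_to_wet()].
#' @param energy_spread Fractional Gaussian spread of each layer's initial
#'   energy (sigma_E / E), default 0.008.
#' @param table A [stopping_power_table()].
#' @return An object of class `"proton_field"`.
#' @export
proton_field <- function(name, energies, weights = NULL,
                         depths_pmma = numeric(), sobp_width = NULL,
                         plateau_dose = 1, cal_doses = NULL, rsp = 1.16,
                         energy_spread = 0.008,
                         table = stopping_power_table()) {
  stopifnot(length(energies) >= 1L)
  if (any(energies < 60 | energies > 250)) {
    stop("layer energies must lie in [60, 250] MeV")
  }
  if (any(depths_pmma < 0)) stop("depths must be non-negative")
  r_layers <- csda_range(table, energies)
  distal <- max(r_layers)
  if (is.null(weights)) {
    if (length(energies) > 1L && !is.null(sobp_width)) {
      weights <- sobp_weights(energies, c(distal - sobp_width, distal - 0.15),
                              energy_spread = energy_spread, table = table)
    } else {
      weights <- rep(1, length(energies))
    }
  }
  stopifnot(length(weights) == length(energies))
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative and not all zero")
  }
  structure(
    list(
      name = name, energies = energies, weights = weights,
      depths_pmma = depths_pmma, sobp_width = sobp_width,
      plateau_dose = plateau_dose, cal_doses = cal_doses, rsp = rsp,
      energy_spread = energy_spread, table = table,
      ranges = r_layers, distal = distal
    ),
    class = "proton_field"
  )
}

#' @export
print.proton_field <- function(x, ...) {
  cat(sprintf(
    "<proton_field> %s: %d layer(s) %.0f-%.0f MeV, distal edge %.2f cm water%s\n",
    x$name, length(x$energies), min(x$energies), max(x$energies), x$distal,
    if (is.null(x$sobp_width)) "" else sprintf(", SOBP width %.1f cm", x$sobp_width)
  ))
  invisible(x)
}

# Straggled-layer moment integrals at water depths z:
#   F  = int phi(R') dR'            (fluence)
#   FS = int phi(R') S(E(R'-z)) dR' (fluence x stopping power, i.e. dose)
#   FS2= int phi(R') S^2 dR'
# phi is the Gaussian range density of the layer; protons with R' < z are
# stopped and contribute nothing. The substitution rho = v^2 clusters
# quadrature nodes at the near-stopping end where S(E(rho)) ~ rho^-0.44.
layer_moments <- function(table, energy, z, energy_spread, n_nodes = 80L) {
  r0 <- csda_range(table, energy)
  sig <- range_sigma(table, energy, energy_spread)
  out <- matrix(0, nrow = 3L, ncol = length(z))
  for (i in seq_along(z)) {
    vmax <- sqrt(max(r0 + 5 * sig - z[i], 0))
    if (vmax <= 0) next
    q <- pracma::gaussLegendre(n_nodes, 0, vmax)
    rho <- q$x^2
    w <- q$w * 2 * q$x
    s_res <- stats::approx(table$log_energy, table$log_value,
                           log(energy_at_residual_range(table, rho)))$y
    s_res <- exp(s_res)
    phi <- stats::dnorm(z[i] + rho, r0, sig)
    out[1L, i] <- sum(w * phi)
    out[2L, i] <- sum(w * phi * s_res)
    out[3L, i] <- sum(w * phi * s_res^2)
  }
  out
}

# summed moments over the field's weighted layers at water depths z
field_moments <- function(field, z_wet) {
  m <- matrix(0, nrow = 3L, ncol = length(z_wet))
  for (k in seq_along(field$energies)) {
    if (field$weights[k] == 0) next
    m <- m + field$weights[k] *
      layer_moments(field$table, field$energies[k], z_wet, field$energy_spread)
  }
  m
}

profile_frame <- function(depths, medium, dose, flet, dlet) {
  structure(
    data.frame(
      depth_cm = depths, medium = medium, dose = dose,
      fluence_let_kev_um = flet, dose_let_kev_um = dlet,
      stringsAsFactors = FALSE
    ),
    class = c("depth_profile", "data.frame")
  )
}

#' Fluence-averaged LET depth profile
#'
#' Fluence-averaged LET in water,
#' f-LET(z) = sum_k w_k int phi_k(R') S(E(R' - z)) dR' /
#'            sum_k w_k int phi_k(R') dR',
#' with Gaussian range-straggling densities phi_k; protons whose straggled
#' range falls short of z contribute no fluence. The result is expressed in
#' keV/um using unit water density (1 MeV cm^2/g -> 0.1 keV/um).
#'
#' Depths where the total fluence vanishes get `NA` LET with a warning
#' rather than a silent zero.
#'
#' @param field A [proton_field()].
#' @param depths_pmma Depths in cm PMMA (default: the field's OSLD depths).
#' @return A `depth_profile` data frame with columns `depth_cm`, `medium`,
#'   `dose` (relative), `fluence_let_kev_um`, `dose_let_kev_um`.
#' @export
fluence_let_profile <- function(field, depths_pmma = field$depths_pmma) {
  stopifnot(inherits(field, "proton_field"))
  z <- pmma_to_wet(depths_pmma, field$rsp)
  m <- field_moments(field, z)
  dead <- m[1L, ] <= 0
  if (any(dead)) {
    warning(sprintf(
      "no proton fluence at %d depth(s); LET undefined there", sum(dead)
    ))
  }
  flet <- ifelse(dead, NA_real_, m[2L, ] / m[1L, ] * 0.1)
  dlet <- ifelse(dead, NA_real_, m[3L, ] / pmax(m[2L, ], .Machine$double.xmin) * 0.1)
  profile_frame(depths_pmma, "pmma", m[2L, ], flet, dlet)
}

#' Dose-averaged LET depth profile
#'
#' Same machinery as [fluence_let_profile()], with the average weighted by
#' dose instead of fluence: LET_d(z) = int phi S^2 / int phi S. Always at
#' least as large as the fluence average (Cauchy-Schwarz).
#'
#' @inheritParams fluence_let_profile
#' @return A `depth_profile` data frame.
#' @export
dose_averaged_let_profile <- function(field, depths_pmma = field$depths_pmma) {
  fluence_let_profile(field, depths_pmma)
}

#' Depth-dose profile
#'
#' Depth dose along the central axis, proportional to the fluence-weighted
#' stopping power summed over layers. `normalize = "plateau"` scales the
#' curve so the mean dose over the SOBP plateau span (single layer: the
#' peak) equals the field's nominal `plateau_dose`.
#'
#' @inheritParams fluence_let_profile
#' @param normalize One of `"plateau"`, `"peak"`, `"none"`.
#' @return A `depth_profile` data frame with `dose` in Gy (or relative for
#'   `"none"`).
#' @export
depth_dose <- function(field, depths_pmma = field$depths_pmma,
                       normalize = c("plateau", "peak", "none")) {
  stopifnot(inherits(field, "proton_field"))
  normalize <- match.arg(normalize)
  prof <- fluence_let_profile(field, depths_pmma)
  scale <- switch(normalize,
    none = 1,
    peak = field$plateau_dose / max(field_moments(
      field, seq(0.05, field$distal + 0.3, by = 0.01)
    )[2L, ]),
    plateau = field$plateau_dose / plateau_dose_level(field)
  )
  prof$dose <- prof$dose * scale
  prof
}

# mean model dose over the plateau span (single layer: peak value)
plateau_dose_level <- function(field) {
  if (is.null(field$sobp_width)) {
    return(max(field_moments(
      field, seq(0.05, field$distal + 0.3, by = 0.01)
    )[2L, ]))
  }
  span <- c(field$distal - field$sobp_width, field$distal - 0.15)
  mean(field_moments(field, seq(span[1L], span[2L], by = 0.1))[2L, ])
}

#' SOBP layer weights for a flat plateau
#'
#' Non-negative least-squares weights making the summed depth dose flat
#' over the requested span, evaluated on a 1 mm depth grid; weights are
#' normalized to a maximum of 1.
#'
#' @param energies Layer energies in MeV.
#' @param span Plateau span in cm of water, `c(lo, hi)`, within the deepest
#'   layer's range.
#' @param energy_spread Fractional initial energy spread, see
#'   [proton_field()].
#' @param table A [stopping_power_table()].
#' @return Non-negative weight vector, max 1.
#' @export
sobp_weights <- function(energies, span, energy_spread = 0.008,
                         table = stopping_power_table()) {
  stopifnot(length(span) == 2L, span[1L] < span[2L])
  if (length(energies) == 1L) return(1)
  if (span[2L] > max(csda_range(table, energies))) {
    stop("plateau span extends beyond the deepest layer's range")
  }
  grid <- seq(span[1L], span[2L], by = 0.1)
  a <- vapply(
    energies,
    function(e) layer_moments(table, e, grid, energy_spread)[2L, ],
    numeric(length(grid))
  )
  w <- pracma::lsqnonneg(a, rep(1, length(grid)))$x
  if (max(w) <= 0) stop("infeasible plateau span: all weights zero")
  w / max(w)
}

#' Sensitivity of the LET to a positioning shift
#'
#' Maximum relative change of the fluence-averaged LET when the measurement
#' point is displaced by `delta_mm` millimetres (geometric, in the PMMA
#' stack) to either side:
#' max over both directions of |LET(z +/- d) - LET(z)| / LET(z).
#'
#' @param field A [proton_field()].
#' @param depth_pmma Measurement depth in cm PMMA.
#' @param delta_mm Displacement in mm of PMMA (default 0.5).
#' @return Relative LET change (dimensionless fraction).
#' @export
shift_sensitivity <- function(field, depth_pmma, delta_mm = 0.5) {
  stopifnot(inherits(field, "proton_field"), length(depth_pmma) == 1L)
  d_cm <- delta_mm / 10
  if (depth_pmma - d_cm < 0) stop("shifted point outside the field extent")
  lets <- fluence_let_profile(
    field, c(depth_pmma, depth_pmma - d_cm, depth_pmma + d_cm)
  )$fluence_let_kev_um
  if (any(!is.finite(lets))) stop("LET undefined at the (shifted) point")
  max(abs(lets[2:3] - lets[1L])) / lets[1L]
}

#' Mid-plateau depth of an SOBP field
#'
#' Midpoint of the SOBP plateau span, returned in cm PMMA.
#'
#' @param field A [proton_field()] with an SOBP width.
#' @return Depth in cm PMMA.
#' @export
mid_plateau_depth <- function(field) {
  stopifnot(inherits(field, "proton_field"), !is.null(field$sobp_width))
  (field$distal - field$sobp_width / 2) / field$rsp
}

#' Write a depth profile to CSV
#'
#' @param profile A `depth_profile` data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_depth_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
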