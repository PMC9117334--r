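# Deterministic pulsed-OSL readout processing: band separation from the
# on/off gates, background subtraction, integral signals, reference
# correction and package statistics.

#' Pulsed-OSL readout curve
#'
#' Per-channel photon counts of one readout: counts accumulated during the
#' stimulation-on gates and during the off gates of each channel. The
#' default binning is 100 channels of 3 s (a 300 s readout), giving exactly
#' 100 on and 100 off data points.
#'
#' @param on,off Per-channel counts (equal length, non-negative).
#' @param channel_width Channel width in seconds.
#' @return An object of class `"posl_curve"`.
#' @export
posl_curve <- function(on, off, channel_width = 3) {
  if (length(on) != length(off)) {
    stop("on and off channel vectors must have the same length")
  }
  if (any(on < 0) || any(off < 0)) stop("counts must be non-negative")
  structure(
    list(
      on = as.numeric(on), off = as.numeric(off),
      channel_width = channel_width,
      total_time = channel_width * length(on)
    ),
    class = "posl_curve"
  )
}

#' @export
print.posl_curve <- function(x, ...) {
  cat(sprintf(
    "<posl_curve> %d channels x %.3g s (total %.3g s), %.4g counts\n",
    length(x$on), x$channel_width, x$total_time, sum(x$on) + sum(x$off)
  ))
  invisible(x)
}

#' Separate the blue and UV emission bands
#'
#' The slow blue band (35 ms lifetime) emits evenly through the on and off
#' gates, so the off-gate counts are attributed to the blue emission; the
#' fast UV band (< 7 ns) only emits during stimulation, so the on-minus-off
#' difference is attributed to the UV band. Negative UV channel values
#' (counting noise) are preserved, not clipped.
#'
#' @param curve A [posl_curve()].
#' @return List with per-channel `blue` and `uv` vectors.
#' @export
separate_bands <- function(curve) {
  stopifnot(inherits(curve, "posl_curve"))
  list(blue = curve$off, uv = curve$on - curve$off)
}

#' Background level of a channel vector
#'
#' Arithmetic mean of the last 10 channels.
#'
#' @param channels Per-channel values (at least 10).
#' @return Background in counts per channel.
#' @export
estimate_background <- function(channels) {
  n <- length(channels)
  if (n < 10L) stop("need at least 10 channels to estimate the background")
  mean(channels[(n - 9L):n])
}

#' Background-subtracted integral signal
#'
#' S = sum over all channels of (channel - background), with the background
#' from [estimate_background()].
#'
#' @param channels Per-channel values (at least 10).
#' @return Net integral S in counts (may be slightly negative from noise).
#' @export
net_integral <- function(channels) {
  sum(channels - estimate_background(channels))
}

#' Band-resolved integral signals of one readout
#'
#' Separates the bands, estimates each band's background from its own last
#' 10 channels, and integrates. The total emission is the net integral of
#' the on-gate counts (everything emitted during stimulation).
#'
#' @param curve A [posl_curve()].
#' @return An object of class `"readout_result"`: list with `s_blue`,
#'   `s_uv`, `s_total` and the per-band background levels.
#' @export
band_signals <- function(curve) {
  bands <- separate_bands(curve)
  structure(
    list(
      s_blue = net_integral(bands$blue),
      s_uv = net_integral(bands$uv),
      s_total = net_integral(curve$on),
      background_blue = estimate_background(bands$blue),
      background_uv = estimate_background(bands$uv)
    ),
    class = "readout_result"
  )
}

#' Reference-corrected signal
#'
#' S / S_R: the field-irradiation integral divided by the integral of the
#' built-in beta reference irradiation of the same detector, cancelling
#' per-detector sensitivity and size differences.
#'
#' @param s Net field signal.
#' @param s_r Net reference signal (> 0).
#' @return The ratio S / S_R.
#' @export
reference_correct <- function(s, s_r) {
  if (any(s_r <= 0)) stop("invalid reference signal: S_R must be positive")
  s / s_r
}

#' UV/blue emission ratio, raw and reference-corrected
#'
#' Raw ratio `S_UV / S_blue`; when a reference readout is supplied, also
#' the corrected ratio `(S_UV / S_R,UV) / (S_blue / S_R,blue)`, in which
#' both per-band sensitivities cancel exactly.
#'
#' @param result A [band_signals()] result for the field irradiation.
#' @param reference Optional [band_signals()] result for the reference
#'   irradiation.
#' @return List with `raw` and (if a reference is given) `corrected`.
#' @export
uv_blue_ratio <- function(result, reference = NULL) {
  if (result$s_blue <= 0) stop("non-positive blue signal")
  out <- list(raw = result$s_uv / result$s_blue)
  if (!is.null(reference)) {
    if (reference$s_blue <= 0 || reference$s_uv <= 0) {
      stop("non-positive reference band signal")
    }
    out$corrected <- (result$s_uv / reference$s_uv) /
      (result$s_blue / reference$s_blue)
  }
  out
}

#' Package statistics of five detector readouts
#'
#' A measurement point is the mean of the five OSLDs of a package with the
#' sample standard deviation (coverage factor k = 1, n - 1 denominator) and
#' the standard error of the mean.
#'
#' @param values Five finite member values.
#' @param n_expected Expected package size (default 5).
#' @return An object of class `"package_measurement"`: list with `values`,
#'   `mean`, `sd`, `sem`, `n`.
#' @export
package_aggregate <- function(values, n_expected = 5L) {
  if (length(values) != n_expected || any(!is.finite(values))) {
    stop(sprintf("expected %d finite member values", n_expected))
  }
  structure(
    list(
      values = values, mean = mean(values), sd = stats::sd(values),
      sem = stats::sd(values) / sqrt(length(values)), n = length(values)
    ),
    class = "package_measurement"
  )
}

#' Spread of per-detector deviations from their package mean
#'
#' Pools the relative deviations d = (v - package mean) / package mean of
#' every detector over all packages and returns their sample standard
#' deviation together with a Gaussian kernel density (Silverman bandwidth)
#' for display. For n detectors per package, independent noise of relative
#' spread s appears here as sigma ~ s * sqrt((n-1)/n).
#'
#' @param values Per-detector values.
#' @param package_id Package membership of each value.
#' @return List with `sigma` (sample SD of the pooled deviations),
#'   `deviations`, and `density`.
#' @export
deviation_spread <- function(values, package_id) {
  stopifnot(length(values) == length(package_id))
  if (length(unique(package_id)) < 2L) stop("need at least 2 packages")
  means <- tapply(values, package_id, mean)
  if (any(means == 0)) stop("degenerate package with zero mean")
  dev <- values / as.numeric(means[as.character(package_id)]) - 1
  list(
    sigma = stats::sd(dev),
    deviations = dev,
    density = stats::density(dev, bw = "nrd0")
  )
}

#' Process every readout of a synthetic dataset
#'
#' Runs [band_signals()] on each proton and reference readout and assembles
#' the per-detector results table used by the calibration and reporting
#' stages.
#'
#' @param dataset A [generate_study()] result (or the `readouts` element of
#'   one, together with `packages`).
#' @return Data frame with one row per detector: `package_id`,
#'   `detector_id`, `s_blue`, `s_uv`, `s_total`, `sr_blue`, `sr_uv`,
#'   `sb_over_ref`, `suv_over_ref`, `ratio_raw`, `ratio_corrected`.
#' @export
process_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  rows <- vector("list", 0L)
  for (pid in names(dataset$readouts)) {
    for (m in dataset$readouts[[pid]]) {
      sig <- band_signals(m$proton)
      ref <- band_signals(m$reference)
      ratios <- uv_blue_ratio(sig, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        package_id = pid, detector_id = m$detector_id,
        s_blue = sig$s_blue, s_uv = sig$s_uv, s_total = sig$s_total,
        sr_blue = ref$s_blue, sr_uv = ref$s_uv,
        sb_over_ref = reference_correct(sig$s_blue, ref$s_blue),
        suv_over_ref = reference_correct(sig$s_uv, ref$s_uv),
        ratio_raw = ratios$raw, ratio_corrected = ratios$corrected,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
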