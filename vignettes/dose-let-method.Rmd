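---
title: "Simultaneous dose and LET estimation with Al2O3:C pulsed OSL: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous dose and LET estimation with Al2O3:C pulsed OSL: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posldose)
```

## The measurement principle

Al2O3:C optically stimulated luminescence detectors (OSLDs) emit in two
bands: a slow blue F-center band (420 nm, 35 ms lifetime) used for
dosimetry, and a fast UV F+-center band (335 nm, < 7 ns) whose intensity
relative to the blue band grows with the ionization density of the
irradiation. Pulsed stimulation (100 µs on / 100 µs off) separates the
bands in time: photons counted during the *off* gates can only come from
the slow blue band, while the on-minus-off difference isolates the fast
UV band. A single detector therefore yields two observables:

* the blue-band integral `S_blue`, related to the absorbed dose;
* the UV/blue ratio, related to the fluence-averaged LET in water
  (f-LET).

Because the blue response is quenched at high ionization density, the LET
estimate feeds back into the dosimetry: the *relative luminescence
efficiency* `eta = D_OSLD,water / D_water` (normalized to 1 in a 230 MeV
proton beam at 2 cm PMMA depth) corrects the quenched dose as
`D_water = D_OSLD,water / eta`.

Each readout is binned into 100 channels of 3 s (criteria for the reader
used here); the background is the mean of the last 10 channels of each
band and is subtracted before integrating. After the proton readout the
detector is re-irradiated by the reader's built-in beta source (30 s,
about 1.4 Gy) and read again, giving per-band reference integrals `S_R`.
The ratio `S/S_R` cancels per-detector sensitivity and size differences;
the reference-corrected UV/blue ratio
`(S_UV/S_R,UV) / (S_blue/S_R,blue)` is the LET observable.

## Calibration forms

Dose and LET calibrations use two empirical functions,

* a saturating exponential `f(x) = a1 (1 - exp(-a2 x)) + a3`, and
* a sigmoid `f(x) = a2 + (a1 - a2) / (1 + a3 x^a4)`,

fitted by Levenberg–Marquardt weighted least squares (weights are inverse
squared package standard errors when available, unweighted otherwise) and
inverted in closed form. The saturating exponential is used for the dose
response (`S/S_R` of the blue band versus dose, 0.1–1.1 Gy) and for
*uncorrected* UV/blue LET calibrations; the sigmoid for the
reference-corrected LET calibration. Initial guesses are scale-free
(`a1 = max(y) - min(y)`, `a2 = 1/median(x)`, `a3 = min(y)`; sigmoid:
asymptotes from the extreme data points), with a small multi-start grid
over the rate parameters because strongly varying package weights can
otherwise trap the optimizer at a boundary. Inversion fails loudly for
values outside the asymptotic bounds rather than extrapolating; the
calibrated LET range of the study ends near 6.5 keV/µm.

The efficiency curve is parameterized against the corrected UV/blue ratio
(not LET), so applying a quenching correction needs no beam model at
inference time. After fitting, the curve is divided by its value at the
calibration condition's ratio, making `eta = 1` there exact by
construction. Efficiency points come from the SOBP-plateau packages only;
single-energy-layer points near the Bragg peak are omitted because
millimetre positioning errors there translate into large dose errors.

## The analytical beam model

Experimental studies of this kind use Monte Carlo transport for dose and
LET; this package ships an analytical stand-in good to a few per cent
for the quantities the chain needs:

* An embedded ~30-node table of proton mass stopping powers of water
  (0.1–250 MeV), log-log interpolated. CSDA ranges are the integral of
  `1/S(E)` on a fine log grid (cutoff 0.1 MeV); the inverse range
  function gives the residual energy at depth.
* Each energy layer is a pencil beam with a Gaussian residual-range
  density: range straggling `sigma_R = 0.012 R^0.935` cm combined in
  quadrature with an initial energy spread of `sigma_E/E = 0.8%`
  (a typical clinical momentum band; the beam-energy accuracy of the
  delivery system is stated as better than 1%).
* f-LET(z) is the fluence-weighted mean of `S(E)` over the surviving
  spectrum; dose is the fluence-weighted sum of `S(E)`; the dose-averaged
  LET weights by `S^2`. The integrals use Gauss–Legendre quadrature with
  a square-root substitution that clusters nodes at the near-stopping end
  of the spectrum, validated against a brute-force range-sampling oracle
  to ~0.1%.
* SOBP layer weights are non-negative least squares fitted on a 1 mm
  grid for a flat plateau over the distal `width` cm; plateau dose
  flatness is below 2%.
* PMMA depths convert to water-equivalent depth with a constant relative
  stopping power of 1.16. Nuclear interactions and secondary protons are
  neglected.

Two consequences of these simplifications are worth knowing. First, the
published irradiation geometry lists OSLD positions slightly beyond the
distal edge that a 1.16 conversion implies for the stated energies; the
default study design therefore places its deepest packages just proximal
of each beam's distal edge. Second, without nuclear secondaries the f-LET
gradient along an SOBP plateau is slightly steeper than full Monte Carlo
transport gives: the 0.5 mm shift sensitivity at the mid-plateau of the
4 cm SOBP evaluates to ~1.3% here, somewhat above the ~1% a
secondary-inclusive simulation shows. Entrance-region LET values are
unaffected (they agree with the reference values within ~5%).

## The synthetic truth model

The generator emulates the statistical structure the analysis relies on,
with defaults chosen once from the study conditions:

* **Study design**: four fields — a 230 MeV calibration field read at
  2 cm PMMA with six doses spanning 0.1–1.1 Gy; a 70 MeV single layer
  (six depths from 1 cm PMMA to just proximal of the peak, doses
  following the depth-dose curve, ~0.2–1 Gy); and two SOBPs (73–112 MeV
  with a 4 cm plateau, 120–177 MeV with 8.5 cm, nine depths each, 1 Gy
  on the plateaus). Thirty packages of five detectors — 150 readout
  pairs, the population size of the reference variability analysis.
* **Detector variability**: per-band sensitivities from a bivariate
  lognormal, CV 10% per band, log-scale correlation 0.5, mean 1.
* **Dose response**: `g(D) = (1 - exp(-0.5 D)) m(D)` with the
  reference-sensitization factor `m(D) = 1 + 0.25 (1 - exp(-D/1.5))`
  folded in. The beta reference signal of a detector previously given a
  proton dose `D` is multiplied by the same `m(D)`, so the corrected dose
  response `S/S_R` versus `D` is *exactly* a saturating exponential —
  the form the dose calibration fits — while both the first readout and
  the reference individually respond non-linearly.
* **LET response**: the truth UV/blue ratio `r(LET)` is exactly of the
  sigmoid calibration form with asymptotes 0.10 and 0.55
  (`a3 = 0.12, a4 = 1.6`), spanning a factor ~3.7 over 0.4–6.5 keV/µm.
  The band efficiency is `eta(L) = (r(0.44) + 1/2) / (r(L) + 1/2)`,
  which is monotone decreasing, equals 1 at the calibration LET, and
  makes the *total* emission during stimulation (UV plus the in-gate
  half of the blue band) exactly LET-independent — the near-constant
  total-emission efficiency seen experimentally. With these choices the
  noiseless chain recovers its generating coefficients to machine-level
  precision, which is what the parameter-recovery tests assert.
* **Readout**: counts deplete as `exp(-t/50 s)` across the 300 s
  stimulation; the blue band splits evenly between on and off gates, the
  UV band falls entirely in the on gates; a 20 counts/channel dark rate
  is added and every channel is Poisson-distributed. The blue-band scale
  is 10^6 counts/Gy, so counting noise (0.1–0.3% per readout at study
  doses) is subdominant to the 10% sensitivity spread. One numerical
  subtlety: with a 50 s depletion constant the last ten channels still
  carry ~0.02% of the signal each, so the background subtraction removes
  ~2.3% of each band integral. The factor is identical for both bands
  and both readouts of a detector and therefore cancels exactly from
  every ratio the method uses.
* **Beta reference**: 1.4 Gy, unquenched (efficiency 1), latent UV/blue
  ratio 0.10; the storage-time build-up of the UV band is taken at its
  two-week plateau (factor 1). The sensitization amplitude is the same
  for both bands: with band sensitivities only 50%-correlated, the
  corrected-ratio-tighter-than-raw ordering already follows from
  sensitivity cancellation, and distinct amplitudes would make the
  corrected ratio dose-dependent, contradicting the exact-recovery
  design of the truth model.

What the generator deliberately does *not* emulate: deep-trap filling
that couples the corrected ratio to dose (the real mechanism limiting
mixed-dose LET accuracy to ~5%), storage-time variation between
packages, temperature effects, and trap-level kinetics. Consequently the
synthetic mixed-dose versus equal-dose LET-accuracy ordering is driven by
counting statistics (low-dose packages have proportionally fewer UV
counts) and its magnitudes (~1% deviations) are smaller than real
measurements show; the tests assert the bound and the ordering, not the
literal magnitudes. Passing tests validate the *chain* — separation,
correction, calibration, inversion, quenching correction and their error
propagation — not the physics completeness of the detector model.

## Numerical and statistical choices

* Package statistics use the sample standard deviation (n−1, coverage
  factor k = 1); points in fits are weighted by the package standard
  error of the mean. Noiseless runs have zero SEMs and fall back to
  unweighted fits.
* The pooled detector-spread statistic is the sample SD of the relative
  deviations from each package's mean; the kernel density (Silverman
  bandwidth) is produced for display only.
* LET uncertainties propagate by the delta method through the inverse
  calibration slope; package LET is the mean of the five member LETs
  with its SEM.
* The efficiency lookup for dose correction is evaluated per detector,
  so its uncertainty contributes to the package spread of corrected
  doses rather than hiding in a common systematic.
* Equal-dose subset: the packages delivered 1 Gy on the two SOBP
  plateaus. LET summary statistics cover packages with true f-LET in
  0.6–6.5 keV/µm, the validated range of the calibration.
* Problem sizes: profiles use 80-node quadrature per layer and depth;
  the default study is 30 packages × 5 detectors × 2 readouts of 100
  channels; a full run takes ~10 s on one core.

## A worked run

```{r run, eval = FALSE}
report <- run_full_study(default_study_config(seed = 1))
report$summary
# mean |LET deviation|: ~0.9% mixed doses, smaller for the 1 Gy subset
report$spreads
# sigma(S) ~ 9% per band -> sigma(S/S_R) ~ 0.3% (blue), 1.6% (UV);
# raw UV/blue ~ 9% -> corrected ~ 1.8%
export_report(report, "study_results")
```

## Known limitations

* The beam model omits nuclear interactions; LET values are a few per
  cent low relative to full transport, covered by the ±10% tolerance of
  the beam-model checks, and plateau LET gradients are slightly steep.
* The efficiency the chain estimates is the dose-domain ratio
  `D_quenched / D_delivered`; with a non-linear dose response this is
  not numerically identical to the signal-domain band efficiency of the
  truth model (they differ by up to ~9% at 1 Gy). The chain is
  self-consistent — it corrects doses with the same quantity it
  calibrates — which is why dose recovery is exact in the noiseless
  limit.
* Calibrations are valid only over the fitted range; out-of-range
  ratios raise errors rather than extrapolating, and the pipeline
  records such detectors as missing estimates.
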