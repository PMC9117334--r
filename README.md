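# posldose

Simultaneous absorbed-dose and LET measurement with Al₂O₃:C pulsed-OSL
detectors in proton beams.

## What this solves

Dosimetry in proton therapy is complicated by ionization quenching: a
luminescent detector under-responds where the linear energy transfer
(LET) is high, i.e. toward the Bragg peak. Al₂O₃:C OSLDs offer a way out
with a single detector: their slow blue F-center emission (35 ms) carries
the dose signal, while the fast UV F⁺-center emission (< 7 ns) grows
relative to the blue band with ionization density. Pulsed stimulation
(100 µs on/off) separates the two in time, so one readout yields

* a dose estimate from the blue band via a saturating-exponential dose
  calibration, `f(D) = a₁(1 − e^{−a₂D}) + a₃`;
* an LET estimate from the UV/blue ratio via a sigmoid LET calibration,
  `f(L) = a₂ + (a₁ − a₂)/(1 + a₃ L^{a₄})`, inverted in closed form;
* a quenching-corrected dose `D_water = D_OSLD,water / η`, where the
  relative luminescence efficiency `η(UV/blue)` is normalized to 1 at
  the 230 MeV calibration condition.

A second, automated beta-source irradiation of each detector provides
per-band reference integrals `S_R`; the ratio `S/S_R` cancels
detector-to-detector sensitivity (a ~10% spread collapses to well below
1%), and the reference-corrected UV/blue ratio makes the LET calibration
usable across different doses.

The package implements the whole chain — band separation, background
subtraction, reference correction, calibrations with inversion and
uncertainty propagation, quenching correction — plus an analytical proton
depth-dose/f-LET model (pristine peaks and SOBPs with range straggling)
and a synthetic detector-population generator that validates the chain
end-to-end. See the methods vignette
(`vignettes/dose-let-method.Rmd`) for the model details.

## A worked example

```r
library(posldose)

# beam model: f-LET at the calibration and entrance conditions
tab <- stopping_power_table()
d1 <- proton_field("d1", 230, depths_pmma = 2.0, table = tab)
fluence_let_profile(d1)$fluence_let_kev_um
#> [1] 0.4226195        # keV/um in water at 2 cm PMMA

f1 <- proton_field("f1", 70, depths_pmma = 1.0, table = tab)
fluence_let_profile(f1)$fluence_let_kev_um
#> [1] 1.106499

# the full synthetic study: 30 packages x 5 OSLDs over four fields
report <- run_full_study(default_study_config(seed = 1))
report
#> <study_report> 30 packages; mean |LET deviation| 0.88% (mixed doses),
#> 0.71% (1 Gy plateaus)

unlist(report$spreads)
#>          sigma_s_blue            sigma_s_uv     sigma_sb_over_ref
#>           0.087329493           0.083244710           0.002767601
#>    sigma_suv_over_ref       sigma_ratio_raw sigma_ratio_corrected
#>           0.016327279           0.087483628           0.018435136

export_report(report, "study_results")   # CSV tables + JSON summary
```

Reading the numbers: the per-band signal spread of ~9% (the synthetic
population's sensitivity CV) collapses to 0.3% (blue) and 1.6% (UV)
after reference correction, and the corrected UV/blue ratio is tighter
than the raw one — the orderings that make automated reference
corrections worthwhile. Package-mean LET estimates deviate from the
beam-model truth by under 1% on average, with the equal-dose (1 Gy
plateau) subset tighter than the mixed-dose set.

A thin command-line wrapper over the same functions is at
`inst/scripts/run_study.R`:

```sh
Rscript inst/scripts/run_study.R --seed 1 --out study_results
```

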