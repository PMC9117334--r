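Package: posldose
Title: Simultaneous Dose and LET Estimation with Al2O3:C Pulsed-OSL Detectors in Proton Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simultaneous measurement of absorbed dose and
    fluence-averaged linear energy transfer (LET) with Al2O3:C optically
    stimulated luminescence detectors (OSLDs) read out in pulsed mode in
    proton beams. Implements pulsed-OSL band separation (blue F-center and
    UV F+-center emission), background subtraction and beta-reference
    signal correction; empirical dose and LET calibration curves
    (saturating-exponential and sigmoid forms) with closed-form inversion;
    ionization-quenching correction through the relative luminescence
    efficiency; an analytical proton depth-dose and LET model (pristine
    Bragg peaks and spread-out Bragg peaks with range straggling); and a
    synthetic detector-population generator for end-to-end validation of
    the full measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
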