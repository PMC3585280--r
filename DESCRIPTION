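Package: rbcwarmup
Title: MR Thermometry Analysis of Red Blood Cell Concentrate Warm-Up
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for proton-resonance-frequency (PRF) MR
    thermometry of red blood cell concentrate (RBC) units warming from
    refrigerated storage toward ambient temperature. Converts drift-corrected
    phase-difference image series to temperature maps, extracts mean, surface
    and core temperature time courses by tangent analysis of volume-fraction
    curves, fits lumped-capacitance and shifted-exponential warm-up models
    with uncertainty propagation, and derives cold-chain quantities such as
    the time of maximal temperature spread, time-to-10-degrees and limiting
    ambient temperatures under the 30-minute rule. A finite-difference pouch
    phantom simulator generates physically consistent synthetic data for
    validation and cohort-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
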