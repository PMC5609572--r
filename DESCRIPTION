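Package: protonQA
Title: Analytical Proton Beam Modelling, SOBP Design and Dosimetry QA for
    Passive Eye-Therapy Beamlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for passive proton-therapy beamline physics
    and quality assurance. Provides Bethe stopping power and CSDA range-energy
    relations for protons in water and thin beamline materials, an analytical
    pristine Bragg-curve generator with Gaussian range straggling, modulator
    wheel weight optimization (non-negative least squares) for flat spread-out
    Bragg peaks, depth-dose and lateral-profile QA metric extraction (range,
    SOBP width, penumbra, homogeneity, symmetry), TRS-398-style absorbed dose
    to water with beam-quality interpolation, radiochromic film netOD
    calibration with third-order polynomials, and track- and dose-averaged
    LET depth curves from per-species fluence spectra. A synthetic beam model
    emulating a 62 MeV ocular proton beamline makes every module testable
    without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr
Config/testthat/edition: 3
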