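Package: muvr
Title: Monte Carlo Monitor-Unit Verification for VMAT Arc Plans
Version: 0.1.0
Authors@R:
    person("MUV", "Maintainers", email = "muvr@example.org", role = c("aut", "cre"))
Description: An independent monitor-unit verification (MUV) pipeline for
    volumetric modulated arc therapy (VMAT) plans. Reads DICOM CT, RT Plan,
    RT Structure Set and RT Dose objects; converts CT Hounsfield units into a
    four-material voxel phantom; decomposes each arc into control-point
    segments with jaw and multi-leaf collimator apertures; transports photons
    through the phantom with a kerma-approximation Monte Carlo engine
    (Woodcock tracking, Klein-Nishina Compton sampling); calibrates engine
    output (Gy/particle) to absolute dose per monitor unit against a water
    reference condition; and evaluates treatment-planning-system dose at
    reference points inside the target volume against a configurable action
    limit. A modified Clarkson sector-integration calculator with
    radiological-depth heterogeneity correction is included as the
    simple-algorithm comparator, and a fixtures module generates every
    synthetic input (CT series, plans, structures, dose grids, phase-space
    files, commissioning tables) needed to exercise the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
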