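Package: cardioEMD
Title: Single-Cell Cardiac Electromechanics and Conductance Sensitivity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates human ventricular myocyte electrophysiology (ten
    Tusscher-Panfilov 2006 variant with a reduced Markov ryanodine receptor)
    coupled one-way to a myofilament contraction model (Rice et al. 2008
    variant), with per-channel maximum-conductance scaling. Provides paced
    single-cell protocols, biomarker extraction (APD90, calcium-transient
    attributes, electromechanical delay), factorial conductance-population
    sweeps over ten channels at four levels and two pacing rates, a fast
    analytic surrogate for testing the sweep machinery, and optimized
    dimensional stacking that embeds the ten-factor results in a 2-D map
    whose axis ordering is chosen to minimize summed absolute neighbor
    differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    png,
    optparse
Config/testthat/edition: 3
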