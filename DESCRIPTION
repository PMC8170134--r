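Package: ventriband
Title: Bi-Ventricular Mechanics Simulation of Pulmonary Valve Replacement
    with Contracting Band Insertion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Idealized magnetic-resonance-style bi-ventricular geometry
    generation, anisotropic modified Mooney-Rivlin constitutive modelling of
    myocardium, scar, patch and band materials, quasi-static large-deformation
    finite-element simulation of the cardiac cycle under prescribed cavity
    pressures, zero-load geometry estimation (preshrink) with secant material
    calibration to imaging volumes, and batteries of pulmonary valve
    replacement band-insertion surgery plans with right-ventricular
    ejection-fraction analysis and exact Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
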