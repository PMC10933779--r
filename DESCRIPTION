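Package: benchmri
Title: Bayesian Estimation of Change in Degenerate Diffusion MRI Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inversion-free inference on changes in the parameters of
    degenerate biophysical models, applied to the three-compartment
    standard model of multi-shell diffusion MRI. Trains per-pattern
    regression models of the derivative distribution of rotation-invariant
    spherical-harmonics summary measures from simulated data, and computes
    posterior probabilities over sparse patterns of parameter change (and
    the amount of change) that best explain an observed change between two
    sets of measurements. Includes the Watson-dispersed stick/zeppelin
    forward model, a NODDI-style constrained-model inversion baseline with
    z-tests, and a simulation harness for confusion-matrix and
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
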