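Package: msdiqsm
Title: Multi-Scale Dipole Inversion for Quantitative Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative susceptibility mapping (QSM) from gradient-echo
    phase using multi-scale dipole inversion: a Laplacian pyramid of
    spherical-mean-value (SMV) preconditioned, nonlinear,
    morphology-constrained dipole deconvolutions with scale-wise dynamic
    error control. Includes Laplacian phase unwrapping, variable-kernel SMV
    background-field removal, derived contrasts (high-pass susceptibility
    mapping, susceptibility-based venography, macro-vessel suppressed maps,
    susceptibility-weighted imaging and intensity projections), evaluation
    metrics with L-curve model selection, and a synthetic phantom generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
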