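Package: retroreg
Title: Reconstructing Covariate Regressions from Case-Control Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the population regression of one explanatory
    variable on another from a retrospective (case-control) sample. Provides
    closed-form selection-bias theory for linear-in-probability and probit
    outcome models (Mills-ratio mean shifts, delta-method approximations,
    slope corrections), a family of slope estimators (stratified, adjusted,
    pooled, inverse-probability-weighted, reconstructed, and an
    inverse-variance combined estimator for the conditional-independence
    case), a first-order odds-ratio correction for paired binary variables,
    and a seeded Monte-Carlo harness that reproduces the reference simulation
    study. Includes a small command-line interface for file-based analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
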