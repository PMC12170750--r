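Package: osteosex
Title: Sex Estimation from Burnt and Unburnt Patellar Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for metric sex estimation from the human patella, with
    particular support for heat-altered (burnt) bone. Implements per-sex
    descriptive summaries and dimorphism tests (skewness, Shapiro-Wilk,
    Levene, Mann-Whitney U with tie-corrected normal approximation),
    Gaussian sectioning points obtained as the intersection of the two
    fitted normal densities together with the D-value area-of-nonoverlap
    statistic, cut-off classification and evaluation of published external
    cut-offs, two-group linear discriminant analysis with unstandardized
    coefficients and leave-one-out cross-validation, and observer-error
    statistics (TEM, relative TEM, coefficient of reliability R). A
    synthetic-data generator emulates paired unburnt/burnt patellae with
    sex-specific heat shrinkage and missingness so every pipeline stage is
    testable without access to restricted skeletal-collection data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
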