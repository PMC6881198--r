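Package: oxyrheo
Title: Oxygen-Dependent Microfluidic Viscometry of Sickle Cell Blood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts pressure-step velocity measurements from a branching
    microfluidic device into oxygen-dependent effective-viscosity rheograms
    and power-law flow behavior indices for sickle cell blood. Models the
    device as a hydraulic resistor network and inverts it by a fixed-point
    scheme, fits shear-thinning power laws, solves a one-dimensional
    multilayer diffusion model of oxygen transport through the device stack,
    simulates transfusion mixing by hemoglobin mass balance, and provides
    nonparametric repeated-measures cohort statistics (Friedman test with
    exact small-sample p values and Bonferroni-corrected pairwise
    sign-permutation tests). A synthetic-data generator with an oxygen- and
    hemoglobin-S-dependent power-law material law stands in for patient
    measurements so that every pipeline stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
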