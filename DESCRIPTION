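Package: mrmediate
Title: Two-Sample Mendelian Randomization Mediation Analysis from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Univariable and multivariable two-sample Mendelian randomization
    (IVW, MR-Egger, weighted median) from GWAS summary statistics, with
    instrument-strength and heterogeneity diagnostics (F and conditional F
    statistics, Cochran's Q and its multivariable adaptation Q_A, Steiger
    directionality filtering), per-variant heterogeneity decomposition
    (radial outlier detection, PRESSO-style global/outlier/distortion
    testing, mixture-model clustering of ratio estimates), and two-step MR
    mediation analysis by the product- and difference-of-coefficients
    methods with delta-method standard errors and proportion mediated.
    Includes allele harmonization for summary statistics, a simulator that
    generates two-sample summary data under a known
    exposure-mediator-outcome causal model with controllable pleiotropy,
    outliers and mechanism clusters, and a pipeline orchestrator with a
    configuration-file interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
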