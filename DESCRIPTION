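Package: connmanova
Title: Multivariate Group Inference for Regional Connectome and Cortical
    Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Four-step multivariate inference for region-wise neuroimaging
    metrics in a two-group, two-sex factorial design. Implements fixed-effects
    multivariate multiple regression with Wilks' lambda omnibus tests and
    Rao's F approximation, leave-one-out partial-F tests for predictor
    contributions, canonical correlation analysis between metric panels and
    the design, per-region response leave-one-out tests with
    Benjamini-Hochberg false discovery rate control, together with total
    intracranial volume normalization, confound residualization, a
    reduced-model test for quadratic age effects, and Welch/chi-squared
    demographic comparisons. Ships a synthetic multi-site cohort generator
    with a plantable sex-by-diagnosis interaction for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'atlas.R'
    'cohort-io.R'
    'demographics.R'
    'preprocessing.R'
    'manova.R'
    'cca.R'
    'simulate.R'
    'pipeline.R'
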