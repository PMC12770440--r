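Package: MOAstrat
Title: Multiobjective Stratification of Clinical Response and Rank-Based
    Feature Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies patients in multi-endpoint intervention studies by
    Pareto nondominated sorting of oriented endpoint changes (V2 - baseline),
    selects extreme best/worst response clusters, and ranks physiological
    parameters associated with response via rank-normalized log-ratios and a
    second-stage nondominated ranking on within-cluster mean and standard
    deviation. Also provides single-endpoint responder classification rules,
    a priori one-way ANOVA power and sample-size computation via the
    noncentral F distribution, and a synthetic cohort simulator with planted
    associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'pareto.R'
    'stratify.R'
    'association.R'
    'cohort.R'
    'transforms.R'
    'synthetic.R'
    'pipeline.R'
    'power.R'
    'show-methods.R'
    'zzz.R'
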