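Package: taguchiCEA
Title: Taguchi Orthogonal-Array Analysis for Controlled-Environment
    Agriculture Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing Taguchi L27(3^k)
    orthogonal-array experiments in controlled-environment agriculture.
    Provides the L27 strength-2 array constructor, signal-to-noise (S/N)
    ratio analysis with larger/smaller/nominal-is-best criteria,
    main-effects tables with delta ranking, additive-model prediction of
    the optimum setting with confirmation-test error rates, two-factor
    interaction screening via cell-mean non-parallelism, chlorophyll
    quantification from absorbance readings, and a synthetic-data
    generator with known multiplicative effects for validating the whole
    pipeline. Ships the complete 27-run lettuce and basil response
    tables from a vertical-farm growth-optimization study as packaged
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: ExperimentalDesign, Agriculture, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
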