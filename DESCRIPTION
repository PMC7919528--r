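Package: acquicost
Title: Plasmid Acquisition Costs from Growth Curves and Conjugation Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the transient growth burden bacteria experience
    immediately after receiving a conjugative plasmid (the acquisition cost)
    and its consequences for plasmid population dynamics. Provides growth
    parameter estimation from plate-reader OD600 curves by the Baranyi,
    modified Gompertz, modified Logistic and smoothed numerical-derivative
    methods with geometric lag times; a time-to-threshold standard curve that
    predicts initial cell densities and expresses the acquisition cost as the
    ratio of predicted to true inoculum; a three-population ordinary
    differential equation model of conjugation (plasmid-free, de novo and
    adapted transconjugants) with serial-transfer simulation; parameter
    inference for the de novo-to-adapted transition rate; and a synthetic
    plate-data generator so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Software, Microbiome, TimeCourse, Regression, MathematicalBiology
RoxygenNote: 7.3.3
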