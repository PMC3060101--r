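Package: dynchase
Title: Differential Dynamic Gene-Expression Analysis of Kinase-Inhibitor
    Chase Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for inhibitor-chase expression time series
    comparing an oncogene-transformed cell line with its parental line.
    Implements cross-array quantile normalization, probe-to-gene collapse,
    a dynamic fold-change prefilter, the between-line log-ratio trajectory
    statistic anchored at the pre-inhibition steady state, and fold-threshold
    calling of oncogene-specific regulation.  Ships a kinetic simulator of
    inhibitor-chase experiments with known ground truth for benchmarking,
    plus calculators for downstream validation assays: Livak delta-delta-Ct
    relative quantification with multiple reference genes, glucose uptake
    normalized to cell number, percent proliferation increase, condition
    fold changes with propagated error, and exponential doubling time.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, limma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
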