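Package: refstab
Title: Reference Gene Stability Analysis and Relative Quantification for RT-qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting stable reference (housekeeping) genes for
    quantitative real-time PCR normalization and for validating them by
    efficiency-corrected relative quantification. Implements replicate-level
    quality control of cycle-threshold (CT) values, amplification-efficiency
    estimation from dilution-series standard curves, four expression-stability
    algorithms (geNorm M value with iterative ranking and pairwise variation,
    a model-based NormFinder-style variance decomposition, BestKeeper
    descriptive statistics, and the comparative delta-CT method), geometric-mean
    aggregation of the four rankings, determination of the optimal number of
    reference genes, and multi-reference efficiency-corrected delta-delta-CT
    fold-change analysis with two-group testing. A seeded CT-data simulator
    with the statistical structure of a two-group qPCR study supports
    end-to-end verification, and a pipeline driver produces machine-readable
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
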