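Package: neuroprog
Title: Transcriptional Program Classification and Disease-Genetics Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genes into neurodevelopmental transcriptional
    programs from timecourse differential-expression tables, and tests
    those programs for disease-genetics signal: conditional
    over-representation of ontology terms with iterative refinement,
    competitive common-variant gene-set enrichment with conditioning,
    exact de novo loss-of-function rate-ratio tests against
    mutation-rate expectations, and single-cell stage profiling of
    program expression.  Includes a synthetic-data generator with known
    ground truth that emulates all pipeline inputs, plus readers and
    writers for GMT, OBO-subset, TSV and MatrixMarket formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
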