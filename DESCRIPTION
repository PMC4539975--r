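Package: robrep
Title: Robust Association Tests for Two-Stage Case-Control Genetic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genotype-based association tests for case-control data that are
    robust to genetic-model misspecification (Cochran-Armitage trend tests,
    Pearson 2-df test, MAX3, MIN2, and the genetic model selection and
    exclusion procedures driven by the Hardy-Weinberg disequilibrium trend
    test), together with the machinery needed to carry them through a
    two-stage genome-wide association design: replication-stage p-values
    that inherit the discovery-stage model choice and risk-allele direction,
    and combined discovery+replication p-values (Fisher and inverse-normal
    combinations) conditioned on first-stage selection. Includes a
    multinomial genotype-count simulator and a type-I-error / power engine
    for two-stage designs, plus a command-line interface over tab-separated
    genotype count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
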