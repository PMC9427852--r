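Package: translatomics
Title: Paired Transcriptome and Translatome Analysis for Single-Cell
    Dual-Omics Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of paired transcriptome and translatome
    sequencing of the same samples, as used to study translational
    regulation in maturing oocytes. Provides TPM quantification from
    gene-level counts, a negative-binomial Wald test for differential
    expression, translation-efficiency (TE) computation and dual-omics
    class assignment, position-weight-matrix scanning of 3'-UTRs with
    exact score p-values and RNA-binding-protein motif enrichment,
    CPE/PAS cis-element detection, ERCC spike-in estimation of
    non-specific capture, contingency statistics for maturation
    outcomes, and a ground-truth-labelled synthetic data generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
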