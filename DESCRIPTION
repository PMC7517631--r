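Package: somtraj
Title: Self-Organizing-Map Trajectory Analysis of Ischemia-Reperfusion Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Condition-trajectory analysis of three-state (pre-ischemia,
    ischemia, reperfusion) bulk RNA-seq designs. Computes TPM from
    transcript-level quantifications, summarizes per-condition expression as
    median log2 TPM, clusters trajectories on a hexagonal self-organizing map
    (batch-trained 7 x 7 grid), selects condition-specific modules into
    ischemia/reperfusion up- and down-regulated clusters by fold-change rules
    on module mean TPM, performs a simplified negative-binomial Wald test for
    differential expression, and tests gene-set over-representation with
    Fisher's exact test and Benjamini-Hochberg adjustment. Includes a
    negative-binomial simulator with planted trajectory classes and gene
    sets so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
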