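Package: snactivity
Title: Single-Nucleus RNA-Seq Analysis of Neuronal Activation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleus RNA-seq studies of
    neuronal activation. Implements sample-level quality control (mapped
    reads, ERCC spike-in correlation, detected-gene count), detection
    proportions with Yates-corrected equal-proportion tests, a-priori
    power analysis via the noncentral t distribution, synthetic pooling
    of nuclei against a bulk reference, two-group differential expression
    by a negative-binomial conditional exact test with
    Benjamini-Hochberg correction, supervised pseudotemporal ordering of
    activation states (independent component analysis plus
    minimum-spanning-tree diameter path), promoter-normalized
    retrotransposon quantification from template-switch-oligo adjacent
    reads, and parent-weighted gene-ontology cosine-similarity networks.
    A synthetic-data module generates cohorts with the statistical
    structure the analysis assumes (activation continuum, dropout, ERCC
    spike-ins, bulk profiles, TSO-tagged reads) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    Matrix,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    edgeR
Config/testthat/edition: 3
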