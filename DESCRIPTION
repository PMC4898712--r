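Package: fragtax
Title: Taxonomic Classification of Randomly Fragmented SSU rRNA Reads and
    PCR Amplification-Bias Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A PCR-independent microbiome analysis toolkit. Classifies
    randomly fragmented reverse-transcribed small-subunit (SSU) rRNA reads
    against a reference taxonomy using quality-region salvage, exact
    dereplication, k-mer (word) similarity search and lowest-common-ancestor
    taxonomy projection, with variable-region screening and reference-based
    chimera detection for amplicon data. Audits 'universal' 16S rRNA PCR
    primer binding sites for per-read mismatches, insertions and deletions
    and rolls them up into per-taxon mismatch ratios. Simulates
    mock-community PCR amplification bias with per-template per-cycle
    efficiencies and its qPCR read-out via standard-curve absolute
    quantification. Ships a synthetic-data generator producing fragmented
    reads with known composition, length distribution, strand mixture and
    error model so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
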