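Package: intronmiR
Title: Discovery and Characterization of Intronic MicroRNAs in Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering small RNAs encoded in the introns of a
    protein-coding gene and characterizing them end to end: enumeration of
    candidate RNA hairpins by sliding-window minimum-free-energy folding under a
    simplified nearest-neighbor model, stability filtering, screening for the
    microprocessor (Drosha/DGCR8) consensus motifs (basal UG, flanking CNNC,
    mismatched GHG, apical UGU/GUG), rule-based extraction of the mature 5p/3p
    duplex with the 2-nt 3' overhang geometry, cross-species conservation
    profiling with guide-strand calling, seed-match target-site scanning over
    3'UTR/CDS/promoter/intron regions, corroboration of predicted targets with
    clone-read local alignment, and relative expression quantification by the
    2^-ddCt (Livak) method. Ships a synthetic-data generator with known truth
    for every stage so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
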