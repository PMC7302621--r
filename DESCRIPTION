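Package: phamnet
Title: Comparative Genomics of Phage Cohorts: Phams, Gene-Content
    Networks, and Intergenic Motifs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparative genomics of annotated phage
    cohorts. Reads GenBank or FASTA genome records; partitions predicted
    proteins into phamilies (phams) by pairwise amino-acid similarity
    with single-linkage closure; computes all-vs-all gene-content
    similarity, fragment-based average nucleotide identity, and MinHash
    nucleotide distance; assigns clusters, subclusters and singletons at
    a shared-gene-content threshold; derives MaxGCDGap isolation scores
    and gene-content/nucleotide-distance genome networks; discovers and
    scans degenerate direct repeats, start-associated motifs, and
    inverted repeats in intergenic regions with case-encoded consensus
    models; and ships a seeded synthetic-cohort generator with truth
    tables so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
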