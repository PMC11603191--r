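Package: hoxr
Title: Hox Gene Complements, Cluster Architecture and Loss History from
    Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homeodomain-encoding Hox loci in nucleotide genome
    assemblies (six-frame scan) and proteomes using calibrated per-orthology-group
    log-odds profiles with Gumbel E-value statistics and an iterative two-round
    search, assigns loci to Hox orthology groups with an explicit ambiguity
    margin, assembles species-by-group complement tables, detects Hox clusters
    and computes their architecture (span, gene order, transcriptional
    orientation, collinearity), counts non-Hox gene interruptions and locates
    mature miRNAs within cluster intervals, and reconstructs gene-loss history
    on a rooted species tree under Dollo parsimony. Ships a seeded synthetic
    genome generator with ground-truth manifests so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
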