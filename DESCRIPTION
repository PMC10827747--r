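Package: submarker
Title: Subspecies Marker-Gene Discovery and Quantification for Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers subspecies-specific marker genes from annotated
    reference genomes via pangenome presence/absence analysis (a gene is a
    marker when present in at least 90% of one subspecies' genomes and in
    none of the sister subspecies), flags mis-annotated reference genomes by
    clustering presence/absence profiles, filters candidate markers for
    cross-species specificity against a decoy gene set, quantifies per-clade
    relative abundance in shotgun metagenomes with a detectability floor and
    an unclassified species-level remainder, builds per-sample strain
    consensus sequences over marker genes with SNP distances and a
    neighbor-joining tree, and checks concordance between computational
    estimates and qPCR delta-delta Ct ratios. A bundled simulator generates
    two-subspecies pangenomes, decoy genes, and error-bearing read mixtures
    with ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    generics,
    ggplot2,
    ape,
    vegan,
    cluster,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    phangorn,
    withr
Config/testthat/edition: 3
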