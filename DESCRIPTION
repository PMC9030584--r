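Package: swnsyn
Title: Synteny Characters and Binary Parsimony for the Swainsonine Gene Cluster
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of the architecture of the swainsonine (SWN)
    biosynthetic gene cluster across fungi. Encodes cluster synteny as binary
    adjacency characters (adjacent gene pairs with canonical vs inverted
    orientation), measures intergenic spans, scans intergenic regions for
    short open reading frames, and infers maximum-parsimony trees of cluster
    architecture with Fitch scoring, exhaustive/branch-and-bound and NNI
    hill-climbing search, per-character change mapping, and Robinson-Foulds
    tree comparison. Ships curated gene-presence and intergenic-region
    character tables for 36 and 14 fungal taxa respectively, and a seeded
    simulator of gene-cluster evolution (loss, adjacent-pair inversion,
    transposition) along Yule phylogenies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    rtracklayer,
    GenomicRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
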