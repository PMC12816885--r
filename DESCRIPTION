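Package: genusdemarc
Title: Genome-Based Genus Demarcation with AAI, POCP and Relative
    Evolutionary Divergence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for delimiting prokaryotic genera from whole-genome
    data. Computes pairwise average amino acid identity (AAI) over
    reciprocal best hits and the percentage of conserved proteins (POCP)
    from per-genome proteomes using a built-in Smith-Waterman search
    engine; locates a genus-level AAI boundary as the local minimum of a
    kernel density estimate with a bandwidth sensitivity sweep; groups
    genomes that satisfy joint AAI/POCP criteria into monophyletic
    clades on a rooted phylogenomic tree with explicit exclusions;
    computes relative evolutionary divergence (RED) for rank
    harmonization; and cross-tabulates marker-gene clade membership
    (e.g. tryptophanase, tnaA) against a binary phenotype such as indole
    production. A synthetic-data generator produces species trees with
    planted genus structure, proteomes whose identity decays with tree
    distance, gene gain and loss, and a clade-restricted marker gene,
    together with truth tables for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    igraph,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
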