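Package: grinscan
Title: Duplication and GRINS Detection and Module Phylogeny for Modular
    Polyketide Synthase Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evolutionary sequence analysis of modular polyketide synthase
    (PKS) gene clusters. Detects intra-cluster duplicated regions by a
    sliding-window all-vs-all identity scan, promotes duplicated regions
    with intense GC and TA nucleotide skews to GRINS calls (genetic
    repeats of intense nucleotide skews), builds neighbor-joining module
    and domain phylogenies from Jukes-Cantor distances over codon-aware
    pairwise alignments, and reports module/domain homology (identity
    matrices, truncated-domain flags). A synthetic-cluster generator
    plants duplications, skewed regions and module families evolved on a
    known tree so that every pipeline stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    seqinr,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
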