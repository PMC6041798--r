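Package: hapquant
Title: Haplotype-Aware Gene and Haplotype Expression from RNA-Seq in
    Polymorphic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates gene- and haplotype-level RNA-seq expression in highly
    polymorphic regions (such as the human MHC) by aligning the same read set
    against a panel of alternate reference haplotypes, weighting each read by
    its edit distance to every haplotype, and selecting the best haplotype
    pair per gene via a switch-penalized shortest path over the gene adjacency
    graph. Includes a deterministic paired-end read simulator and a small
    seed-and-verify exhaustive aligner so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
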