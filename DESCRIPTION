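Package: tpscan
Title: Genome-Wide Characterization of Terpene Synthase Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of
    terpene synthase (TPS) gene families from genome sequences and gene
    models: spliced coding-sequence assembly and translation, exon/intron
    architecture and intron-phase analysis, TPS class assignment from intron
    counts, splice-boundary consensus matrices with information content,
    degenerate protein motif compilation and scanning, protein
    physicochemical properties (molecular weight, isoelectric point),
    pairwise identity and paralog detection, neighbor-joining phylogeny with
    bootstrap support and reference-anchored subfamily assignment, tandem
    gene cluster detection, and RPKM expression summaries. Includes a
    seeded synthetic-genome simulator with planted ground truth for
    validating the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, Annotation, SequenceMatching, Phylogenetics,
    GeneExpression
RoxygenNote: 7.3.3
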