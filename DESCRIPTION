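Package: kinomeEvo
Title: Plant Kinome Annotation, Duplication, Selection and Coexpression Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of plant protein kinase (PK)
    superfamilies. Identifies kinase genes from profile-HMM domain-hit
    tables using E-value and model-coverage filters, classifies them into
    groups and families, and summarizes gene structure (kinase-domain
    multiplicity, intron counts, chromosomal distribution). Detects tandem
    duplicate arrays by an intervening-gene/physical-distance rule and
    segmental duplicates by collinear anchor chaining, estimates Ka and Ks
    for duplicate pairs with the Nei-Gojobori (1986) counting method under
    a Jukes-Cantor correction, classifies alternative-splicing events from
    transcript models, clusters FPKM expression profiles by k-means under
    Pearson correlation distance, and builds thresholded Pearson
    coexpression networks. A synthetic-data module generates genomes,
    codon-diverged CDS pairs, isoform sets and expression matrices with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Annotation, GeneExpression, Network, Clustering
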