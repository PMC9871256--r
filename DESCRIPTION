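Package: nlratlas
Title: Genome-Wide Annotation and Analysis of the NLR Disease-Resistance Gene Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of plant NLR
    (nucleotide-binding site leucine-rich repeat, NBS-LRR) disease-resistance
    genes from standard annotation and homology-search outputs. Covers
    E-value filtering and homology screening of NBS candidates, domain
    architecture classification into the CNL, TNL and RNL subclasses,
    presence calling of the conserved NBS motifs (P-loop, kinase-2, RNBS-B/C/D,
    GLPL, MHDV) with position-specific score matrices, physical gene-cluster
    detection under a genomic distance rule, duplicate-type classification
    (tandem, proximal, dispersed, segmental) with rank-space collinearity
    chaining, neighbor-joining phylogenies with bootstrap support, and a
    resistant-versus-susceptible FPKM expression screen. A synthetic-genome
    generator plants known architectures, clusters, duplication types,
    syntenic blocks and expression fold changes so every stage can be scored
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
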