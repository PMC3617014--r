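Package: tnrscan
Title: Cross-Species Analysis of Tri-Nucleotide Repeats and Homo-Amino-Acid Tracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and scoring of short-period tandem repeat tracts in
    DNA under an exact wraparound-alignment score, localization of tracts to
    gene regions, classification of protein homo-amino-acid tracts as
    tri-nucleotide-repeat- or variant-encoded by codon back-mapping, and the
    accompanying statistical battery: chi-squared tests of repeat unit
    frequencies against an order-2 Markov genomic background, exact binomial
    composition tests, Mann-Whitney length comparisons, interaction-degree
    and conservation comparisons, and Gene Ontology over-representation with
    transitive-closure annotation propagation against custom backgrounds.
    Includes a fully seeded synthetic-data generator (genome, gene models,
    proteome, ontology, interactions, conservation track) with ground-truth
    tables, so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
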