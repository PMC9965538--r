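Package: phagetax
Title: Genus-Level Taxonomy and Genome-Feature Analysis for Kuravirus-Like Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reimplementation of a genome-based taxonomy and
    characterization pipeline for Kuravirus-like Escherichia phages.
    Provides a seed-and-extend local alignment engine producing
    high-scoring segment pairs (HSPs), VIRIDIC-style intergenomic
    similarity with ICTV species/genus threshold clustering, a
    shared-protein-cluster viral network with hypergeometric edge
    weighting and Markov clustering, Genome-BLAST Distance Phylogeny
    (GBDP) distances with neighbor-joining trees, pseudo-bootstrap
    supports and OPTSIL-style fraction-of-links clustering, genome
    feature analyses (direct terminal repeat detection from long reads
    and assemblies, programmed -1 ribosomal frameshift isoform
    prediction, codon-usage bias against a host), pangenome ortholog
    clustering with core-proteome extraction, and a synthetic
    phage-genome and nanopore-like read simulator so that every stage
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    Matrix,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
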