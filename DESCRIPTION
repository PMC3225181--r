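Package: cliquemotif
Title: De Novo DNA Motif Discovery by Merging Maximal Cliques of a
    k-mer Similarity Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-theoretic discovery of cis-regulatory binding-site
    motifs of a fixed length k in unaligned DNA sequences. Input
    sequences are decomposed into overlapping 2(k-1)-mer windows that
    become the vertices of a weighted similarity graph; edge weights are
    the maximum Hamming match count over all k-mer pairs between two
    windows. One greedy maximal weighted clique is found per vertex,
    overlapping cliques are merged around a core clique, and the merged
    group is refined into a set of similar k-mer sites reported as a
    motif. The approach is designed to recover motifs whose nucleotide
    composition is close to that of the background, which
    composition-contrast methods tend to miss. Also includes a
    third-order Markov background simulator with binding-site
    implantation for planted-motif benchmarking, and site-level
    sensitivity/specificity/performance-coefficient scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
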