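Package: fmofam
Title: Motif-Based Classification and Phylogeny of Class B Flavoprotein
    Monooxygenases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for the comparative analysis of class B
    flavoprotein monooxygenases (flavin-containing monooxygenases, FMOs;
    Baeyer-Villiger monooxygenases, BVMOs; N-hydroxylating monooxygenases,
    NMOs). Detects the two Rossmann-fold dinucleotide-binding motifs and the
    FMO-identifying motif in protein sequences, assigns sequences to ten
    family groups from diagnostic motif residues and N-terminal domain
    architecture, builds per-family position frequency matrices and consensus
    strings, runs a pattern-constrained homolog search with Karlin-Altschul
    e-values and abundance binning, reconstructs neighbor-joining trees with
    bootstrap support and monophyly and sister-clade tests, and tabulates
    per-taxon homolog abundance and co-occurrence. Ships a synthetic corpus
    generator emulating the family-specific three-motif architecture so the
    whole pipeline is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
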