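Package: auxevol
Title: Evolutionary Analysis of the Aux/IAA Gene Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the expansion and molecular evolution of the
    plant Aux/IAA transcriptional-repressor family and similar multi-gene
    families. Provides motif discovery under a zero-or-one-occurrence-per-
    sequence (ZOOPS) expectation-maximization model, consensus and
    position-weight-matrix scanning, motif-composition typing of family
    members, nuclear localization signal (bipartite and SV40-like)
    classification, tandem/segmental duplication calling from gene
    coordinates and collinearity blocks, protein-guided codon alignment with
    Ka/Ks estimation by Nei-Gojobori (NG86) counting and a modified
    Yang-Nielsen (MYN) approximate method, neighbor-joining phylogenies with
    bootstrap supports and sister-pair extraction, the accompanying summary
    statistics, and a codon-level simulator of gene families with known
    duplication history for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
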