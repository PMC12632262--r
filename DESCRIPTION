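Package: psrcov
Title: Comparative Sequence Analysis of Receiver and Pseudo-Receiver Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of bacterial receiver-domain
    multiple sequence alignments. Classifies aligned domains as receivers or
    pseudo-receivers (PsRs) from the five conserved active-site residues
    (DD1, DD2, D, T, K, anchored to E. coli CheY numbering), computes
    position-wise amino-acid composition profiles and between-group difference
    matrices, performs corrected (average-product correction) mutual-information
    covariation analysis with z-score significance and percentile ranks,
    extracts core and extended covariation networks with best-neighbor backbone
    annotation and per-position hub scores, and compares covariation between
    sequence groups by percentile rank shifts. Includes a synthetic alignment
    generator with tunable landmark conservation, composition biases, and
    planted covarying column blocks so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
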