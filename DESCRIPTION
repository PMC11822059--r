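Package: cisprime
Title: Design and Quantification Toolkit for Dual Cis-Nick Prime Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Enumerates and assembles guide-RNA constructs for prime editing
    with two cis nicks on the same DNA strand: an upstream nicking sgRNA
    (ups-sgRNA) and an extended pegRNA (ext-pegRNA) whose primer binding site
    anneals to the 3' end created by the upstream nick, optionally with a
    third Helper gRNA between the two nicks for large edits. Implements the
    geometric constraints on the distance between cis nicks (DCN), the edit
    sequence / homologous sequence (ES/HS) decomposition of the reverse
    transcriptase template, and flap-complementarity mismatch engineering;
    mechanistically replays the editing pathway to predict the product
    allele; and classifies amplicon sequencing reads by global alignment to
    quantify intended edits, indels and product purity. Includes seeded
    synthetic locus and read generators so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
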