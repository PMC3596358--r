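Package: madevol
Title: Divergence, Selection and Tree Congruence in Fungal Adhesin Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for the Metarhizium
    adhesin genes Mad1 (insect adhesion) and Mad2 (plant adhesion) and the
    5' EF-1alpha species-diagnostic locus.  Computes pairwise global-alignment
    divergence with inter-/intraspecies summaries, Nei-Gojobori dN/dS with
    pathway averaging and Jukes-Cantor correction, maximum-parsimony trees
    with SPR branch swapping and nonparametric bootstrap, maximum agreement
    subtrees with the Icong congruence index and its random-tree null
    calibration, promoter scanning for STRE/PDS/TATA-like elements and
    degenerate-TATA repeat arrays, protein translation with tandem-repeat
    annotation, and a seeded codon-level sequence simulator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
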