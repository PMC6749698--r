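Package: secscreen
Title: Analysis Pipeline for Chaperone-Assisted Protein Secretion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the computational workflow of
    bacterial chaperone/amylase co-expression screens: label-free Hi3 (top-3
    peptide) relative quantification of membrane proteins from peptide-level
    intensity tables, percent-identity matrices of mature protein sequences by
    local Smith-Waterman alignment with neighbor-joining trees, degenerate
    promoter and operator motif scanning on both strands, microplate kinetic
    assay calibration and Miller-unit computation, and reference-normalized
    relative-yield statistics with Bonferroni-corrected pairwise tests. A
    synthetic-data module generates every input the pipeline consumes with
    known ground truth, so the full workflow is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
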