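Package: pairedTCR
Title: Paired-Chain Single-Cell TCR Repertoire Analysis for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-cell T cell receptor (TCR) repertoire analysis in
    paired (e.g. pre/post intervention) cohort designs. Reads 10x Genomics
    contig annotations or AIRR Rearrangement tables, pairs alpha and beta
    chains per cell, calls clonotypes under several key definitions, and
    quantifies clonal structure: size-bin occupancy, unique-clone fractions,
    CDR3 length spectra, diversity and evenness indices (Shannon, inverse
    Simpson, Gini-Simpson, normalized entropy, Chao1, ACE) with bootstrap
    downsampling, Morisita-Horn repertoire overlap, CDR3 positional
    composition/entropy/Atchley-factor profiles and k-mer spectra, TRAV-TRBV
    pairing contingency arrays with stratified Cochran-Mantel-Haenszel tests
    and per-pair Fisher exact tests with odds ratios, and edit-distance
    clonal clustering. Includes a seeded synthetic paired-cohort generator
    with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
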