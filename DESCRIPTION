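Package: codonstab
Title: Codon and Amino Acid Determinants of mRNA Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how coding-sequence composition relates to mRNA decay.
    Computes codon and amino acid usage profiles from CDS FASTA files, codon
    stability coefficients (CSC) and amino acid stabilization coefficients
    (AASC) against transcript half-life tables, tRNA adaptation indices (tAI)
    from tRNA-seq read counts with median-based codon optimality calls, and
    transcript-level average stability scores. Designs synonymous
    codon-flipped reporter sequences at a target optimality, fits
    per-transcript half-lives from spike-in normalized metabolic-labeling
    decay timecourses by least absolute deviations with growth-dilution
    correction, and provides the downstream association models (optimality
    versus GC3 exact tests, half-life and CSC regressions, stratified and
    two-group rank comparisons). A synthetic-data generator with a truth
    manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    readr,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
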