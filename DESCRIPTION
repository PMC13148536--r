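Package: codonopt
Title: Codon Optimality, Non-Optimal Codon Preference, and Protein
    Surface Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies codons as optimal or non-optimal from the
    difference in relative synonymous codon usage (RSCU) between a highly
    expressed reference gene set and the genome background, stratifies
    codons by exact-match tRNA gene copy number, classifies genes by
    sex-biased expression and tissue specificity (tau), detects
    preferentially used ("primary") non-optimal codons from gene-set
    RSCU contrasts, and links non-optimal codon use to per-residue
    relative solvent accessibility (RSA), including an exact sign test
    across the 18 degenerate amino acids. A synthetic-data module
    generates coding sequences, expression matrices, tRNA tables and
    residue-level structure tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
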