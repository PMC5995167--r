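Package: asexdiv
Title: Comparative Molecular Evolution of Sexual and Asexual Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genomic consequences of the loss of
    recombination in asexual lineages, using paired comparisons of sexual
    and asexual sister species. Implements per-gene base-composition
    statistics (GC3, UTR GC content), branch-specific equilibrium GC
    estimation under a nonstationary two-state substitution model with a
    likelihood-ratio test against the stationary model, parsimony-based
    mapping of synonymous substitutions into weak-to-strong,
    strong-to-weak and GC-conservative categories, pooled-read SNP
    filtering and pN/pS estimation, per-branch dN/dS by Nei-Gojobori
    counting on a fixed species tree, codon-usage-bias statistics
    (effective number of codons, codon deviation coefficient), and a
    permutation-ANOVA inference layer. A codon-level simulator generates
    alignments and pooled-population pileups along an annotated species
    tree with branch-specific selection efficacy, GC-biased gene
    conversion and reproductive-mode-specific polymorphism, so every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
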