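Package: codonbias
Title: Amino Acid and Codon Usage Bias, Relative Entropy, and
    Mixed-Model Regression for Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes per-genome composition profiles from coding
    sequences: nucleotide, codon and amino-acid frequencies, genomic
    %AT, amino acid usage bias (AAUB) and codon usage bias (CUB) as the
    empirical standard deviation of the 20 and 64 frequencies, and the
    Kullback-Leibler relative entropy of codon frequencies against the
    zeroth-order (factorized) null implied by genomic base composition.
    Provides correlation-matrix PCA and complete-linkage clustering of
    frequency matrices, linear models of %AT on codon frequencies,
    phylum-level ANOVA of usage bias, and generalized additive mixed
    models with nested phylum/genus/species random intercepts and %AT
    random slopes, compared by AIC. Includes a synthetic-cohort
    generator with nested taxonomy, a wide %AT gradient and a tunable
    exponential codon tilt with closed-form relative entropy, so every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
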