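Package: odontotrace
Title: Ancestral Armour Reconstruction and Saturation-Aware Dataset Reduction for Catfish Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to trace the evolution of trunk odontodes and dermal bony
    plates across the catfish suborder Loricarioidei and its outgroups.
    Implements constrained k-state Markov (Mk) models with transition-rate
    equality classes, Felsenstein pruning likelihoods on time-calibrated
    trees, multi-restart maximum-likelihood fitting, and marginal ancestral
    state reconstruction; plus the substitution-saturation reduction series
    in which protein-coding genes are translated to amino acids and the
    fastest discrete-gamma rate categories of ribosomal RNA sites are
    identified by empirical-Bayes classification under GTR+Gamma and removed.
    Ships a 23-family chronogram fixture, simulators for ultrametric trees,
    GTR+Gamma site columns with known rate categories, and discrete
    characters with known ancestral states, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    phangorn,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
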