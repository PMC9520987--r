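Package: mrnets
Title: Causal Networks from Mendelian Randomization with Genetic Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Moves from classical Mendelian randomization (MR) to causal
    networks over omic entities. Constructs genetic instruments (single
    variants or polygenic factors from PCA/MCA of a genotype dosage matrix),
    fits classical MR designs (first-stage prediction, multivariable MR, Wald
    ratios, two-step mediation, two-sample MR), identifies an MR-constrained
    causal network with a PC-style constraint-based learner whose edges are
    oriented by a conditional-independence pleiotropy screen, selects the
    learner's tuning parameter by minimizing average Hamming distance across
    subsamples, and assesses the fitted network with four stability
    diagnostics (confounding-equivalence, variable-reduction,
    variable-increment, permutation). Ships a linear-Gaussian structural
    equation model simulator with Hardy-Weinberg genotypes, latent
    confounders, injectable pleiotropy, and a downstream trait, so every
    method is testable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
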