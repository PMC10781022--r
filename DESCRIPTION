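Package: finemapvi
Title: Bayesian Fine-Mapping of GWAS Loci with Functional Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-maps causal variants from GWAS summary statistics and
    linkage-disequilibrium (LD) matrices using a sum-of-single-effects
    sparse regression model fitted by paired mean-field variational
    inference. Hyperparameters are set from local heritability estimated
    with an eigenvalue-truncated LD pseudo-inverse. Effect groups are
    summarised into rho-level credible sets filtered by attainable
    coverage, and binary functional annotations can sharpen the prior
    inclusion probabilities through jointly estimated enrichment weights
    screened with a G-test. Includes an LD-structured genotype and trait
    simulator, evaluation metrics (AUPRC, credible-set coverage/power/size,
    PIP calibration, prior log relative ratio), a sliding-window
    genome-wide driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
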