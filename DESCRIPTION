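Package: pepremc
Title: Replica Exchange Monte Carlo Design of Peptide Binders from Docking Scores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolves short peptide binders in sequence space with a replica
    exchange Monte Carlo (parallel tempering) kernel driven by stochastic
    docking-like scores, and post-processes the scores into comparable binding
    energies. Includes the single-point mutation move, Metropolis acceptance on
    scores, a three-temperature ladder with per-step swap attempts,
    mutation-off multi-docking rescoring, a negative-control-corrected binding
    energy statistic with summed standard errors, and dissociation-constant to
    free-energy conversion with error propagation. A seeded synthetic additive
    score landscape with Gaussian per-docking noise makes the whole pipeline
    testable without an external docking engine; an adapter contract carries
    docking box metadata for engines such as AutoDock Vina.
License: MIT
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
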