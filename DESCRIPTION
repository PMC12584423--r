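Package: flexvar
Title: Bayesian Variance Partitioning of Among- and Within-Individual
    Behavioral Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits double-hierarchical Gaussian mixed models to repeated
    behavioral measurements, partitioning phenotypic variance into
    among-individual and within-individual (behavioral flexibility)
    components that may differ across population-by-sex groups. Provides a
    conjugate Gibbs sampler, a four-model candidate set over the variance
    structure, WAIC and Pareto-smoothed importance-sampling leave-one-out
    model comparison, repeatability and posterior contrast tables, a
    synthetic-study generator for parameter-recovery experiments, and a
    configurable end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
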