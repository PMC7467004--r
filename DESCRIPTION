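Package: convmode
Title: Composite-Likelihood Inference of Modes of Convergent Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits coalescent-based composite-likelihood models of convergent
    adaptation to population allele-frequency data. Given allele frequencies
    at putatively neutral sites and at a putatively selected region across
    several selected and non-selected populations, the package estimates the
    neutral coancestry matrix, transforms it under competing sweep models
    (independent mutations, migration from a source population, standing
    variation with or without a source, and mixed modes over population
    subsets), evaluates the composite log-likelihood over a user-specified
    parameter grid, and returns maximum-composite-likelihood estimates in a
    uniform tidy table. Includes a model-consistent synthetic-data generator
    for power and recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
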