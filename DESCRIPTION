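Package: choosiness
Title: Phylogenetic Multilevel Meta-Analysis of State-Dependent Mate Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the strength of animal mate choice
    depends on the chooser's individual state (age, attractiveness, body
    size, condition, mating status, parasite load). Converts raw study
    statistics (correlations, two-group tests, group summaries, 2x2
    frequency tables) into signed Fisher-Z effect sizes with sampling
    variance 1/(n-3), pairs them with a Grafen-calibrated species tree,
    and fits four-level random-effects meta-analytic models (phylogeny,
    species, study, observation) by restricted maximum likelihood.
    Includes I-squared heterogeneity partitioning across levels,
    categorical moderator meta-regression with QM tests and marginal
    R-squared, Egger-type publication-bias tests and bias-adjusted mean
    effects, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
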