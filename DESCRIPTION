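Package: traitsuccession
Title: Trait-Based Analysis of Microbiome Succession with Phylogenetic
    Hidden-State Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of longitudinal microbiome
    cohorts. Builds ultrametric 16S trees by agglomerative clustering,
    curates sparse literature-derived trait tables, predicts missing tip
    trait values by weighted squared-change parsimony, subtree averaging
    and independent contrasts, gates predictions by phylogenetic trait
    conservatism (model competition against a far-pair null expectation),
    computes community-weighted trait means and variances, classifies
    taxa into successional groups, measures taxonomic (Bray-Curtis) and
    trait-space turnover and cross-host convergence, and tests trait-based
    statistics against trait-shuffling null ensembles. Includes a
    synthetic-data generator emulating a longitudinal infant-gut cohort
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
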