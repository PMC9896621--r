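Package: posevote
Title: Docking-Augmented Machine Learning for Ligand Bioactivity
    Classification
Version: 0.1.0
Authors@R:
    person("posevote", "developers", email = "posevote@example.org",
           role = c("aut", "cre"))
Description: Turns multiple docked poses per compound into binary
    ligand-receptor contact fingerprints over a fixed binding-site atom
    axis, combines them with docking scoring-function values, filters
    poses by consensus top-20% voting and heavy-atom RMSD deduplication,
    classifies bioactivity with a panel of machine learners (random
    forest, gradient boosting, naive Bayes, k-nearest neighbours,
    probabilistic neural network, multilayer perceptron), refines
    descriptors by two-phase genetic-algorithm selection with Cohen's
    kappa as fitness and a SHAP class-consistency filter, translates the
    surviving contacts into rule-based structure pharmacophores, and
    triages virtual-screening hits by an active-pose-ratio threshold.
    Ships a synthetic-fixture generator with a planted contact-activity
    association so the full pipeline is testable without any docking
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
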