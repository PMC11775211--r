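Package: phenorank
Title: Ontology-Based Differential Diagnosis of Rare Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks rare diseases for a patient's set of phenotype terms
    against a disease-phenotype annotation knowledge base organized on a
    directed acyclic ontology (such as the Human Phenotype Ontology).
    Implements an information-content overlap similarity (ICTO), a naive
    Bayes model with probability propagation in the ontology (PPO), few-shot
    classifiers (complement naive Bayes and a single-hidden-layer perceptron
    with Mixup and random-perturbation augmentation), an order-statistics
    rank-aggregation ensemble, classical semantic-similarity baselines, a
    synthetic ontology/knowledge-base/case generator, and an evaluation
    harness with top-k recall, median rank, bootstrap confidence intervals
    and signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
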