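Package: SurvNN
Title: Neural Network Cox Models for Transcriptomic Survival Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Survival prognosis from gene-expression cohorts with neural
    network Cox proportional hazards models. Implements the Cox partial
    likelihood as a differentiable training loss shared by three
    architectures (a single-hidden-layer Cox network, a multi-layer
    feed-forward Cox network, and an autoencoder whose bottleneck code
    feeds a Cox regression head), together with expression preprocessing
    (gene filtering, log transform, per-gene min-max scaling),
    confound-balanced train/validation/test split selection, Sobol
    quasi-random hyperparameter search, Harrell concordance and log-rank
    evaluation, k-medoids stratification of the learned latent space, and
    tumor mutation burden correlation analyses. Includes a seeded synthetic
    cohort simulator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    cluster,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
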