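# SurvNN

Neural network Cox proportional hazards models for cancer survival
prognosis from bulk transcriptomes.

Predicting which patients face a higher risk of death from their tumor's
gene-expression profile is a standard task in cancer genomics, and the
Cox model is its statistical workhorse: patient *i* has hazard
*h*(t | X<sub>i</sub>) = *h*₀(t) · exp(η<sub>i</sub>), and the partial
likelihood

  L = ∏<sub>i: C_i = 1</sub> exp(η<sub>i</sub>) / Σ<sub>j: Y_j ≥ Y_i</sub> exp(η<sub>j</sub>)

depends only on the relative risks, so any differentiable network can
supply η. SurvNN implements the negative log partial likelihood as a
training loss (Breslow ties, analytic gradients, full-batch Adam) shared
by three architectures:

| family | architecture | loss |
|---|---|---|
| `coxnnet` | one tanh hidden layer → hazard head | −ℓ(η) + λ‖Θ‖₂² |
| `deepsurv` | 1–4 equal-width ReLU/SELU layers → hazard head | −ℓ(η) + λ‖Θ‖₂² |
| `aecox` | mirror-symmetric autoencoder; tanh(code) → hazard head | λ₁·MSE + (1−λ₁)(−ℓ(η)) + λ₂‖Θ‖₁ + λ₃‖Θ‖₂² |

Around the models the package provides the full study pipeline:
expression filtering / log transform / per-gene min–max scaling,
confound-balanced 60/20/20 split selection (1000 scored shuffles, 5 folds
kept by a five-component balance score), Sobol quasi-random
hyperparameter search with an exact budget, Harrell concordance and
log-rank evaluation, PAM clustering of the learned latent space with
silhouette-selected k, tumor-mutation-burden summaries and correlation
analyses, and a seeded synthetic cohort simulator so everything runs
without external data. It is aimed at computational biologists studying
survival learnability across cohorts and at methodologists who need a
transparent, fully testable neural-Cox reference implementation in R.

## Worked example

Simulate a 300-patient cohort with a two-factor latent survival signal,
preprocess it, pick a balanced split, train an AECOX model, and evaluate
on the held-out test set:

```r
library(SurvNN)

cfg <- simConfig(nSamples = 300, nGenes = 80, latentRank = 2,
                 beta = c(1.2, 1.2), censoringRate = 0.3, seed = 11)
cohort <- simulateCohort(cfg)
pp <- preprocessCohort(cohort)
pp
#> SurvCohort: 58 genes x 300 samples
#>   events: 210 deceased / 90 censored (30.0% censoring)
#>   os_months: median 21.9, range 0.0-586.3
#>   TMB counts attached
#>   preprocessed: TRUE

split <- selectBalancedSplits(pp, nShuffles = 200, nKeep = 1, seed = 2)[[1]]
X <- t(exprValues(pp)); tt <- survTime(pp); ev <- survEvent(pp)

spec <- archSpec("aecox", hiddenSizes = 16L, seed = 3)
m <- trainModel(buildModel(spec, ncol(X)),
                X[split@train, ], tt[split@train], ev[split@train],
                X[split@validation, ], tt[split@validation], ev[split@validation])

risk <- predictRisk(m, X[split@test, ])
concordanceIndex(risk$eta, tt[split@test], ev[split@test])
#> [1] 0.8044833
logrankTest(medianDichotomize(risk$theta), tt[split@test], ev[split@test])
#> $statistic 25.101, $p.value 5.44e-07
```

A test concordance of 0.80 means 80% of evaluable patient pairs are
ranked correctly by predicted risk (0.5 would be chance); the log-rank p
says the median-dichotomized high- and low-risk groups have clearly
separated survival curves. The learned latent space stratifies patients
too:

```r
emb <- extractLatent(m, X)                       # 300 x 16 bottleneck code
sel <- selectKBySilhouette(emb)                  # k chosen in 2..10
clusterSurvivalTest(sel$assignment, tt, ev, subset = split@test)
#> k = 2, avg silhouette 0.521; chi2 40.5, p = 1.97e-10
```

A command-line front end with `simulate`, `preprocess`, `split`, `train`,
`evaluate`, `cluster`, and `benchmark` subcommands is installed at
`inst/scripts/survnn` (see `survnn --help`).

## Package layout

- `R/` — S4 classes (`SurvCohort`, `CohortSplit`, `ArchSpec`,
  `NeuralSurvModel`), the Cox partial-likelihood core and Newton solver,
  the neural engine with manual back-propagation, preprocessing, split
  selection, Sobol search, PAM latent analysis, benchmark statistics, and
  the cohort simulator.
- `tests/testthat/` — unit, property, and end-to-end suites; every
  numerical claim is checked against an independent oracle (closed forms,
  `survival::coxph`, brute-force enumeration, Monte-Carlo).
- `vignettes/neural-cox-methods.Rmd` — the methods vignette: model
  details, numerical choices, generator assumptions, limitations.
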