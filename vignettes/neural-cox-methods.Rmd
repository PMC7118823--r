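---
title: "Neural network Cox models: methods and design notes"
author: "SurvNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural network Cox models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SurvNN)
```

# The model

SurvNN predicts relative survival risk for cancer patients from bulk
gene-expression profiles. The statistical backbone is the Cox proportional
hazards model: patient $i$ with covariates $X_i$ has hazard

$$h(t \mid X_i) = h_0(t)\, \theta_i, \qquad \theta_i = \exp\!\Big(\sum_k \beta_k X_{ik}\Big),$$

and the baseline hazard $h_0(t)$ cancels from the partial likelihood

$$L(\beta) = \prod_{i: C_i = 1} \frac{\theta_i}{\sum_{j: Y_j \ge Y_i} \theta_j},$$

where $Y_i$ is the follow-up time, $C_i = 1$ marks an observed death, and
the denominator runs over the risk set (everyone still under observation at
$Y_i$, patient $i$ included). Because only $\theta_i$ enters, any
differentiable function can replace the linear predictor: SurvNN trains
feed-forward networks whose scalar output $\eta_i$ plays the role of
$\sum_k \beta_k X_{ik}$, minimizing the negative log partial likelihood

$$-\ell(\eta) = \sum_{i: C_i = 1} \Big[\log \sum_{j: Y_j \ge Y_i} e^{\eta_j} - \eta_i\Big]$$

by back-propagation. Three architectures share this loss:

* **coxnnet** — one tanh hidden layer (width 131–135 in the published
  configuration; the package default is 133) feeding a linear hazard head.
  Regularized with an L2 penalty $\lambda\|\Theta\|_2^2$; its single
  hyperparameter makes a 12-point line search sufficient.
* **deepsurv** — one to four hidden layers of one common width (30–50 at
  the last layer), ReLU by default with SELU available, same L2-penalized
  loss.
* **aecox** — a mirror-symmetric autoencoder (0/2/4/6/8 total hidden
  layers, ReLU with dropout) with a linear bottleneck code of width 16.
  The code, through a tanh, feeds the Cox head, and training minimizes

$$\lambda_1\,\mathrm{MSE}(X_{in}, X_{out}) + (1-\lambda_1)\,(-\ell(\eta)) + \lambda_2\|\Theta\|_1 + \lambda_3\|\Theta\|_2^2,$$

  so reconstruction quality and survival fit are balanced by
  $\lambda_1 \in [0,1]$ and $\lambda_2, \lambda_3$ form an elastic net
  ($\lambda_2 = 0$, the ridge-only regime, is the default).

Only relative risks are identified: the loss is invariant under a constant
shift of $\eta$, and no baseline hazard is estimated anywhere in the
package. Tied event times use the Breslow convention (tied events share a
risk-set denominator) — the common choice in neural Cox implementations,
and the one that keeps the gradient cheap.

# Training procedure and numerical choices

* **Optimizer.** All families train with Adam. The original
  implementations used a different optimizer per family (Nesterov
  accelerated gradient, plain SGD, Adam); optimizer identity is not part
  of the model mathematics, so the package standardizes on one adaptive
  method and exposes learning rate and epoch budget per family (defaults
  4000 / 500 / 300 epochs for coxnnet / deepsurv / aecox).
* **Batching.** Full-batch by default: the partial-likelihood risk set at
  each event must see every patient still at risk, and sub-batching
  truncates it. A mini-batch mode exists for large cohorts but computes
  risk sets within the batch and warns that this is a biased
  approximation.
* **Epoch selection.** When a validation set is supplied, the weight
  snapshot with the best validation concordance is kept, which guards
  against late-epoch overfitting without a separate early-stopping rule.
* **Initialization and determinism.** Fan-in-scaled Gaussian weights,
  inverted dropout, and all shuffling derive from the integer seed in the
  `ArchSpec`; two runs with the same spec and data are bit-identical.
  Dropout is disabled at inference, so prediction and latent extraction
  are deterministic.
* **Numerical safety.** The log-sum-exp in the loss is computed after
  centring $\eta$ at its maximum (shift invariance makes this free).
  Non-finite training loss aborts with a learning-rate hint. Zero-event
  inputs return loss 0 with a warning (the empty product) rather than
  erroring, so degenerate batches never crash a run.
* **Gradient correctness.** The analytic gradient of the loss — through
  the Breslow cumulative hazard for the data term and manual
  back-propagation for every architecture — is checked against central
  differences in the test suite, and the linear special case (no hidden
  layer, identity activation, $\lambda = 0$) is required to reproduce the
  Newton–Raphson maximum-partial-likelihood estimate.

The classical estimator itself ships as `fitLinearCox()`: Newton–Raphson
with step halving on $-\ell(X\beta) + \lambda\|\beta\|_2^2$. Constant
covariate columns are reported as non-identifiable (coefficient 0, with a
warning); with $\lambda = 0$ a monotone likelihood (perfect risk
separation) is detected by coefficient divergence (threshold 15 on the
coefficient magnitude — the gradient decays exponentially in $|\beta|$, so
a runaway fit can masquerade as converged) and reported as an error
advising a positive penalty.

# Preprocessing

The pipeline is filter → log → scale, in that order:

1. `filterGenes()` removes the 20% of genes with the lowest mean absolute
   expression, then the 10% of the *remaining* genes with the lowest
   variance. The two stages are sequential with floor counts and stable,
   input-order tie-breaking.
2. `logTransform()` applies $\log(x + 1)$ to the non-negative normalized
   expression values.
3. `minmaxScaleGenes()` maps each gene row to $[0, 1]$ so every gene
   enters the model on an equal scale; constant rows map to zeros with a
   warning instead of dividing by zero.

Min/max statistics are computed on the full cohort before the splits are
drawn. This mirrors the upstream protocol (preprocessing precedes split
selection) but is a mild form of information sharing across the eventual
test set; it affects only the per-gene affine scale, not the outcome, and
is flagged here as a known caveat.

# Confound-balanced splits

Each cohort is divided 60/20/20 into training/validation/testing
(train $= \mathrm{round}(0.6n)$, validation $= \mathrm{round}(0.2n)$,
test $=$ remainder). To avoid confounding between the partitions, 1000
random shuffles are scored and the 5 best are retained as folds. The score
is the sum of five standard deviations across the three partitions: male
fraction, SD of overall-survival time, mean of overall-survival time,
deceased fraction, and — per tumor-stage level — the SD of that level's
fraction, summed over levels. Two conventions are worth noting, both
chosen because the literal alternatives are ill-defined:

* the "male/female ratio" is computed as the male *fraction*
  (males / (males + females)); a literal quotient is infinite when a
  partition happens to contain no females, whereas a fraction is always
  defined and absent levels simply contribute 0;
* the stage term handles an arbitrary number of levels by summing one SD
  per level.

`selectBalancedSplits()` is deterministic given its seed, and the test
suite re-scores the identical shuffle stream by brute force to confirm
the retained splits are exactly the stream's five lowest scores.

# Evaluation

* `concordanceIndex()` implements Harrell's c-index: permissible pairs are
  those whose earlier time is an event (or tied times with exactly one
  event — the censored patient demonstrably outlived the other); tied risk
  scores count 1/2; tied times with two events are not permissible. 0.5 is
  chance, 1 is perfect ranking. The implementation is checked against the
  `survival` package's concordance on censored data.
* `medianDichotomize()` labels a patient high-risk iff its score is
  *strictly* above the median — deterministic for odd cohorts and tied
  medians — and the resulting two groups (or the latent clusters, below)
  are compared with `logrankTest()`, a wrapper over
  `survival::survdiff()` returning the $\chi^2$ statistic with $G-1$
  degrees of freedom. `kaplanMeier()` exposes the product-limit curve for
  reporting.

# Hyperparameter search

Multi-dimensional spaces are explored with an unscrambled Sobol sequence:
`q` low-discrepancy points (default 100) cover the unit cube, are mapped
to each dimension's scale (affine for linear, geometric for log, rounded
for integer, index-selected for categorical), and each candidate is
trained once and scored by validation concordance — cost $O(nq)$
regardless of dimension. The generator is implemented in the package from
primitive-polynomial direction numbers (12 dimensions supported) rather
than delegated to an external solver, so the point stream is fully
reproducible from the source; scrambling is off by default for the same
reason. The 1-D coxnnet space uses a 12-point line search instead,
log-spaced over $\lambda$ by default since ridge weights act on a
multiplicative scale (configurable).

# Latent-space stratification

The last hidden layer (or the aecox code) is a learned low-dimensional
representation of the transcriptome. `pamCluster()` applies k-medoids
(PAM) under Euclidean distance via `cluster::pam`, augmented with seeded
random restarts: the swap phase only guarantees a single-swap local
optimum, and restarts make reaching the global optimum far more reliable
(for $n \le 12$ an exhaustive mode enumerates every medoid set and serves
as the test oracle). `selectKBySilhouette()` picks $k \in [2, 10]$ by
maximal average silhouette width, with singleton clusters assigned
silhouette 0 by the usual convention. Clustering is fit on all samples'
embeddings, but `clusterSurvivalTest()` evaluates the K-group log-rank on
the testing subset only, so the reported separation is out-of-sample; the
joint-fit/test-only-evaluate choice is configurable through the `subset`
argument.

# The synthetic cohort generator

Every stage of the pipeline is testable offline against
`simulateCohort()`, which emulates the structure the models assume:

* **Expression** — $X = \exp(\mu_g + L Z + \varepsilon)$ with $r$ standard
  normal latent factors $Z$, Gaussian loadings, gene intercepts
  $\mu_g \sim U(1, 4)$, and log-scale noise (SD 0.3 by default). The
  exponential link keeps values strictly positive while preserving the
  recoverable low-rank structure; defaults emulate normalized RSEM-style
  magnitudes.
* **Survival** — exponential event times with rate
  $h_0 \exp(\beta^\top Z_i)$ (the proportional-hazards mechanism;
  $h_0 = 0.02$/month puts median survival near 35 months, typical of the
  bulk tumor cohorts emulated) and independent exponential censoring whose
  rate is solved numerically so the expected censoring fraction hits the
  target (30% by default, in the range of the TCGA-style cohorts that
  motivate the package).
* **Clinical** — sex Bernoulli(0.5); stage over four levels with
  probabilities (0.25, 0.35, 0.25, 0.15), loosely following large
  solid-tumor cohorts.
* **TMB** — negative-binomial counts (dispersion 5, geometric-mean 100)
  whose log mean tracks the standardized true risk with a configurable
  coupling in $[-1, 1]$.

What the generator does *not* emulate: negative-binomial count noise at
the gene level, batch effects, non-proportional hazards, informative
censoring, and missing clinical fields. Tests passing on this generator
therefore demonstrate correctness of the algorithms under the model's own
assumptions, not robustness to the full messiness of real RNA-seq
cohorts.

The TMB study surrogate (`tmbCorrelationStudy()`) builds a family of
cohorts along a malignancy gradient — rising mean TMB accompanied by a
higher baseline hazard and a weaker expression–risk signal — and checks
that mean TMB correlates negatively with mean test concordance across
cohorts. This reproduces the *direction* of the reported
burden-vs-learnability association by construction; it does not, and is
not meant to, reproduce any particular correlation magnitude from real
pan-cancer data.

# Problem sizes used in the shipped studies

The package's own tests and the acceptance script run at simulation sizes
chosen to make every statistical property measurable while keeping a
full run in the minutes range: cohorts of 100–500 samples with 20–120
genes for training studies, $n = 1000$ for the random-risk calibration
(50 Monte-Carlo repeats), 1000 scored shuffles for the split protocol,
six scenario cohorts per TMB replicate study with ten seeded replicates.
At these sizes the strong-signal cohorts give a true-risk ceiling around
concordance 0.8, and all three families train to within 0.05 of it.

# Known limitations

* Full-batch training holds the whole cohort in memory; cohorts far above
  $10^4$ samples would need the (biased) mini-batch mode or a
  case-control approximation of the risk sets.
* The Breslow tie convention slightly biases coefficients when ties are
  heavy; Efron's correction is deliberately out of scope.
* Only right censoring is supported; no time-dependent covariates, no
  competing risks.
* The two-way ANOVA and linear mixed-effects comparisons that complement
  the paired t-tests in pan-cancer reporting are external analyses
  (standard tooling, e.g. `nlme`) and are not re-implemented here.
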