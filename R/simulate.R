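#' Simulation configuration for synthetic cohorts
#'
#' Bundles the generator settings for a synthetic expression/survival
#' cohort with the statistical structure the pipeline assumes: a
#' non-negative expression matrix with low-rank latent structure (the
#' exponential of a rank-`latentRank` Gaussian model, emulating normalized
#' RSEM-style values), proportional-hazards survival times driven by the
#' latent factors, independent exponential censoring calibrated to a
#' target censoring fraction, sex/stage covariates, and optional TMB
#' counts coupled to the true risk.
#'
#' @param nSamples Cohort size (>= 10).
#' @param nGenes Number of genes.
#' @param latentRank Rank r of the latent structure.
#' @param beta Effect vector of length `latentRank` on the latent factors;
#'   the true linear predictor is \eqn{\eta^* = \beta^\top Z}.
#' @param baselineRate Exponential baseline hazard (events per month);
#'   default 0.02 puts the median survival of an average patient near 35
#'   months, in the range typical of the bulk tumor cohorts this emulates.
#' @param censoringRate Target censoring fraction in \[0, 1).
#' @param noiseSd SD of the Gaussian gene-level noise on the log scale.
#' @param tmbCoupling Correlation sign/strength in \[-1, 1\] between log
#'   TMB mean and the true risk.
#' @param seed Integer seed.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(nSamples = 200, nGenes = 500, latentRank = 2,
                      beta = rep(1, latentRank), baselineRate = 0.02,
                      censoringRate = 0.3, noiseSd = 0.3,
                      tmbCoupling = 0, seed = 1L) {
  if (nSamples < 10) stop("nSamples must be at least 10")
  if (latentRank > nGenes) stop("latentRank cannot exceed nGenes")
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must lie in [0, 1)")
  if (abs(tmbCoupling) > 1) stop("tmbCoupling must lie in [-1, 1]")
  if (length(beta) != latentRank) stop("beta must have length latentRank")
  structure(list(nSamples = nSamples, nGenes = nGenes,
                 latentRank = latentRank, beta = beta,
                 baselineRate = baselineRate, censoringRate = censoringRate,
                 noiseSd = noiseSd, tmbCoupling = tmbCoupling,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a low-rank non-negative expression matrix
#'
#' Draws latent factors \eqn{Z} (r x n, standard normal), gene loadings,
#' and gene-level noise, and maps
#' \eqn{X = \exp(\mu_g + L Z + \epsilon)} so values are strictly positive
#' with recoverable rank-r structure (the exponential link preserves
#' non-negativity without truncation).
#'
#' @param config A [simConfig()].
#' @return A list with `expr` (genes x samples, dimnames set) and `Z`
#'   (r x n latent factors).
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(config$seed)
  n <- config$nSamples; G <- config$nGenes; r <- config$latentRank
  Z <- matrix(stats::rnorm(r * n), r, n)
  L <- matrix(stats::rnorm(G * r, sd = 0.6), G, r)
  mu <- stats::runif(G, 1, 4)
  E <- matrix(stats::rnorm(G * n, sd = config$noiseSd), G, n)
  expr <- exp(mu + L %*% Z + E)
  dimnames(expr) <- list(sprintf("gene%04d", seq_len(G)),
                         sprintf("sample%04d", seq_len(n)))
  colnames(Z) <- colnames(expr)
  list(expr = expr, Z = Z)
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times are exponential with rate
#' \eqn{h_0 \exp(\beta^\top Z_i)}; censoring times are independent
#' exponentials whose rate is calibrated numerically so the expected
#' censoring fraction matches the target. A target of 0 yields all events.
#'
#' @param Z r x n latent factor matrix.
#' @param beta Effect vector (length r).
#' @param baselineRate Baseline hazard (per month).
#' @param censoringRate Target censoring fraction in \[0, 1).
#' @param seed Integer seed.
#' @return A list with `time`, `event`, and the true predictor `etaStar`.
#' @export
simulateSurvival <- function(Z, beta, baselineRate = 0.02,
                             censoringRate = 0.3, seed = 1L) {
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(seed)
  etaStar <- drop(crossprod(Z, beta))
  rates <- baselineRate * exp(etaStar)
  eventTime <- stats::rexp(length(rates), rate = rates)
  if (censoringRate <= 0) {
    return(list(time = eventTime, event = rep(1L, length(rates)),
                etaStar = etaStar))
  }
  # expected censoring fraction for censor rate c: mean over i of c/(rate_i + c)
  target <- function(logc) mean(exp(logc) / (rates + exp(logc))) - censoringRate
  logc <- stats::uniroot(target, lower = log(min(rates)) - 20,
                         upper = log(max(rates)) + 20)$root
  censTime <- stats::rexp(length(rates), rate = exp(logc))
  list(time = pmin(eventTime, censTime),
       event = as.integer(eventTime <= censTime),
       etaStar = etaStar)
}

#' Simulate per-sample tumor mutation burden counts
#'
#' Negative-binomial counts whose log mean tracks the true risk
#' \eqn{\eta^*} with the requested sign and strength: the standardized
#' risk is multiplied by `coupling` (scaled to give a log-mean SD of 1 at
#' |coupling| = 1) before exponentiation.
#'
#' @param etaStar True linear predictors.
#' @param coupling Value in \[-1, 1\]; 0 gives TMB independent of risk.
#' @param meanCount Marginal geometric-mean count (default 100).
#' @param size Negative-binomial dispersion (default 5).
#' @param seed Integer seed.
#' @return Integer vector of non-negative counts.
#' @export
simulateTMB <- function(etaStar, coupling = 0, meanCount = 100, size = 5,
                        seed = 1L) {
  if (abs(coupling) > 1) stop("coupling must lie in [-1, 1]")
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(seed)
  z <- if (stats::sd(etaStar) > 0) scale(etaStar)[, 1] else etaStar * 0
  mu <- meanCount * exp(coupling * z)
  as.integer(stats::rnbinom(length(etaStar), mu = mu, size = size))
}

#' Simulate clinical covariates
#'
#' Sex is Bernoulli(0.5) male/female; tumor stage is categorical over four
#' levels (I--IV) with fixed probabilities (0.25, 0.35, 0.25, 0.15),
#' loosely following the stage mix of large solid-tumor cohorts.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return data.frame with columns `sex`, `stage`.
#' @export
simulateClinical <- function(n, seed = 1L) {
  if (n < 1) stop("n must be positive")
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(seed)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "male", "female")
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.25, 0.35, 0.25, 0.15))
  missing <- setdiff(c("I", "II", "III", "IV"), unique(stage))
  if (length(missing))
    message("stage level(s) absent from the simulated cohort: ",
            paste(missing, collapse = ", "))
  data.frame(sex = sex, stage = stage, stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs the expression, survival, clinical, and (optionally) TMB
#' generators under one configuration and assembles a
#' [SurvCohort-class]. The ground truth (latent factors, effect vector,
#' true risk) is kept in the object metadata for oracle-style evaluation.
#'
#' @param config A [simConfig()].
#' @param withTMB Attach simulated TMB counts (default TRUE).
#' @return A [SurvCohort-class]; `metadata(x)$truth` holds `Z`, `beta`,
#'   `etaStar`.
#' @export
simulateCohort <- function(config, withTMB = TRUE) {
  stopifnot(inherits(config, "simConfig"))
  ex <- simulateExpression(config)
  sv <- simulateSurvival(ex$Z, config$beta, config$baselineRate,
                         config$censoringRate, seed = config$seed + 1L)
  cl <- simulateClinical(config$nSamples, seed = config$seed + 2L)
  clinical <- data.frame(sample_id = colnames(ex$expr),
                         os_months = sv$time, event = sv$event,
                         sex = cl$sex, stage = cl$stage,
                         stringsAsFactors = FALSE)
  tmb <- if (withTMB)
    stats::setNames(simulateTMB(sv$etaStar, config$tmbCoupling,
                                seed = config$seed + 3L),
                    colnames(ex$expr))
  else NULL
  cohort <- SurvCohort(ex$expr, clinical, tmb = tmb)
  S4Vectors::metadata(cohort)$truth <-
    list(Z = ex$Z, beta = config$beta, etaStar = sv$etaStar)
  S4Vectors::metadata(cohort)$config <- config
  cohort
}
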