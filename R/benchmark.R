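#' Run a multi-dataset, multi-model survival benchmark
#'
#' For every (dataset, model family, fold): trains on the fold's training
#' set (optionally after a hyperparameter search scored on the validation
#' set), predicts risk on the held-out test set, and records the Harrell
#' concordance index and the p-value of the two-group log-rank test after
#' median dichotomization of the predicted hazard ratios. Folds are the
#' confound-balanced splits from [selectBalancedSplits()] (5 per dataset
#' by default, so each cohort is evaluated 5 times). A failed cell is
#' recorded with `NA` metrics and the run continues.
#'
#' @param cohorts Named list of [SurvCohort-class] objects (raw cohorts
#'   are preprocessed on the fly).
#' @param families Character vector of model families.
#' @param nSplits Folds per dataset (default 5).
#' @param nShuffles Shuffles scored during split selection (default 1000).
#' @param search If `TRUE`, run [searchHyperparams()] per cell; otherwise
#'   train the family's default architecture.
#' @param q Search budget when `search = TRUE`.
#' @param specArgs Named list of fixed [archSpec()] overrides (e.g.
#'   `list(maxEpochs = 100L)` for a reduced-budget run).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A `data.frame` with columns `dataset`, `model`, `fold`,
#'   `cindex`, `logrank_p`, `seed` (one row per cell).
#' @export
runExperiment <- function(cohorts, families = c("coxnnet", "deepsurv", "aecox"),
                          nSplits = 5, nShuffles = 1000, search = FALSE,
                          q = 100, specArgs = list(), seed = 1L) {
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("dataset", seq_along(cohorts))
  rows <- list()
  for (dn in names(cohorts)) {
    cohort <- cohorts[[dn]]
    if (!cohort@preprocessed) cohort <- preprocessCohort(cohort)
    X <- t(exprValues(cohort))
    time <- survTime(cohort); event <- survEvent(cohort)
    splits <- selectBalancedSplits(cohort, nShuffles = nShuffles,
                                   nKeep = nSplits, seed = seed)
    for (fam in families) {
      for (fold in seq_along(splits)) {
        sp <- splits[[fold]]
        cellSeed <- (seed * 1000L + fold * 10L +
                       match(fam, c("coxnnet", "deepsurv", "aecox"))) %% .Machine$integer.max
        res <- tryCatch({
          tr <- sp@train; va <- sp@validation; te <- sp@test
          spec <- if (search) {
            sr <- searchHyperparams(
              fam, XTrain = X[tr, , drop = FALSE], timeTrain = time[tr],
              eventTrain = event[tr], XVal = X[va, , drop = FALSE],
              timeVal = time[va], eventVal = event[va], q = q,
              specArgs = c(specArgs, list(seed = cellSeed)))
            sr$bestSpec
          } else do.call(archSpec, c(list(family = fam, seed = cellSeed),
                                     specArgs))
          model <- trainModel(buildModel(spec, ncol(X)),
                              X[tr, , drop = FALSE], time[tr], event[tr],
                              X[va, , drop = FALSE], time[va], event[va])
          risk <- predictRisk(model, X[te, , drop = FALSE])
          ci <- concordanceIndex(risk$theta, time[te], event[te])
          lr <- tryCatch(
            logrankTest(medianDichotomize(risk$theta), time[te], event[te])$p.value,
            error = function(e) NA_real_)
          c(ci, lr)
        }, error = function(e) {
          message("cell (", dn, ", ", fam, ", fold ", fold, ") failed: ",
                  conditionMessage(e))
          c(NA_real_, NA_real_)
        })
        rows[[length(rows) + 1L]] <-
          data.frame(dataset = dn, model = fam, fold = fold,
                     cindex = res[1], logrank_p = res[2], seed = cellSeed,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Paired t-test between two models' metrics
#'
#' Classical paired Student's t-test on per-(dataset, fold) metric
#' differences, the statistic used to compare model families across
#' cancers and folds. Incomplete pairs (either side `NA`) are excluded
#' pairwise with a logged count.
#'
#' @param a,b Numeric metric vectors paired by position.
#' @return A list with `t`, `df`, `p.value`, `nPairs`.
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  ok <- !is.na(a) & !is.na(b)
  if (sum(!ok) > 0) message(sum(!ok), " incomplete pair(s) excluded")
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: paired t statistic undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, nPairs = length(a))
}

#' Tumor mutation burden summary statistics
#'
#' Mean, median, max, and the 20/10/5% upper-tail cut values (the 80th,
#' 90th, and 95th percentiles, linear interpolation between order
#' statistics) of per-sample mutation counts. Any log2 transform is a
#' reporting convenience only; summaries are computed on the raw counts.
#'
#' @param counts Non-negative per-sample mutation counts.
#' @return Named numeric vector: `mean`, `median`, `max`, `tail20`,
#'   `tail10`, `tail5`.
#' @export
tmbSummary <- function(counts) {
  if (length(counts) < 1) stop("need at least one sample")
  if (any(counts < 0)) stop("mutation counts must be non-negative")
  qs <- stats::quantile(counts, c(0.80, 0.90, 0.95), names = FALSE, type = 7)
  c(mean = mean(counts), median = stats::median(counts), max = max(counts),
    tail20 = qs[1], tail10 = qs[2], tail5 = qs[3])
}

#' Correlation between two study-level quantities
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value, used e.g. for mean TMB versus mean concordance across
#' datasets.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `rho` and `p.value`.
#' @export
correlateMetrics <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Append TMB as a model feature
#'
#' Adds one min-max-scaled TMB row to a preprocessed expression matrix for
#' the with-TMB-feature condition. Samples lacking a TMB value are dropped
#' from both inputs with a logged count (the retained cohort is the
#' intersection of samples with expression and TMB data).
#'
#' @param cohort A preprocessed [SurvCohort-class] with `tmb` in its
#'   colData (samples with `NA` TMB are dropped).
#' @return The cohort restricted to the TMB intersection, with one extra
#'   feature row `TMB` appended to the assay.
#' @export
tmbFeatureAugment <- function(cohort) {
  stopifnot(is(cohort, "SurvCohort"))
  tmb <- tmbCounts(cohort)
  if (is.null(tmb)) stop("cohort carries no TMB counts")
  keep <- which(!is.na(tmb))
  if (length(keep) == 0) stop("no samples with both expression and TMB data")
  if (length(keep) < ncol(cohort))
    message(ncol(cohort) - length(keep), " sample(s) without TMB dropped")
  cohort <- cohort[, keep]
  tmb <- tmbCounts(cohort)
  rng <- diff(range(tmb))
  scaled <- if (rng == 0) rep(0, length(tmb)) else (tmb - min(tmb)) / rng
  m <- rbind(exprValues(cohort), TMB = scaled)
  cd <- SummarizedExperiment::colData(cohort)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = m), colData = cd)
  out <- new("SurvCohort", out, preprocessed = cohort@preprocessed)
  S4Vectors::metadata(out) <- S4Vectors::metadata(cohort)
  out
}

#' TMB-versus-learnability scenario study
#'
#' Generates a family of synthetic cohorts along a malignancy gradient --
#' increasing mean TMB goes with a higher baseline hazard (shorter
#' survival) and a weaker expression-risk signal (lower achievable
#' concordance) -- runs the survival benchmark on each, and correlates
#' mean TMB with mean test concordance across cohorts. This is the
#' desk-scale surrogate for the observed negative TMB/concordance
#' correlation: the study design fixes the direction of the confounding,
#' and the pipeline is expected to recover a negative correlation sign.
#'
#' @param nDatasets Cohorts along the gradient (default 6).
#' @param nSamples,nGenes Per-cohort size (defaults 120, 60).
#' @param nSplits Folds per cohort (default 2).
#' @param families Model families to run (default `"coxnnet"`).
#' @param specArgs [archSpec()] overrides for the benchmark (default a
#'   compact network and a reduced epoch budget, sized for simulation
#'   studies).
#' @param seed Master seed.
#' @return A list with `byDataset` (mean TMB, TMB summaries, mean
#'   concordance per cohort), `pearson` and `spearman` correlation
#'   results, and the raw `results` table.
#' @export
tmbCorrelationStudy <- function(nDatasets = 6, nSamples = 120, nGenes = 60,
                                nSplits = 2, families = "coxnnet",
                                specArgs = list(hiddenSizes = 8L,
                                                maxEpochs = 150L),
                                seed = 1L) {
  if (nDatasets < 3) stop("need at least 3 datasets to correlate")
  grad <- seq(0, 1, length.out = nDatasets)
  cohorts <- lapply(seq_len(nDatasets), function(i) {
    g <- grad[i]
    cfg <- simConfig(nSamples = nSamples, nGenes = nGenes, latentRank = 2,
                     beta = rep(1.6 * (1 - g) + 0.05, 2),
                     baselineRate = 0.01 * exp(2.5 * g),
                     censoringRate = 0.3, noiseSd = 0.3,
                     tmbCoupling = 0.3,
                     seed = seed * 100L + i)
    cohort <- simulateCohort(cfg)
    # malignancy gradient: mean TMB rises along the scenario family
    cd <- SummarizedExperiment::colData(cohort)
    cd$tmb <- as.integer(round(cd$tmb * exp(2 * g)))
    SummarizedExperiment::colData(cohort) <- cd
    cohort
  })
  names(cohorts) <- sprintf("scenario%02d", seq_len(nDatasets))
  results <- runExperiment(cohorts, families = families, nSplits = nSplits,
                           nShuffles = 50, specArgs = specArgs, seed = seed)
  meanC <- tapply(results$cindex, results$dataset, mean, na.rm = TRUE)
  meanTMB <- vapply(cohorts, function(co) mean(tmbCounts(co)), numeric(1))
  byDataset <- data.frame(dataset = names(meanC),
                          meanTMB = meanTMB[names(meanC)],
                          meanCIndex = as.numeric(meanC))
  list(byDataset = byDataset,
       pearson = correlateMetrics(byDataset$meanTMB, byDataset$meanCIndex,
                                  "pearson"),
       spearman = correlateMetrics(byDataset$meanTMB, byDataset$meanCIndex,
                                   "spearman"),
       results = results)
}

#' Write / read a benchmark result table
#'
#' Comma-separated with header `dataset,model,fold,cindex,logrank_p,seed`;
#' the round trip is lossless.
#'
#' @param results data.frame from [runExperiment()].
#' @param path File path.
#' @return Invisibly `path` (writer); the data.frame (reader).
#' @export
writeResultTable <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a benchmark report
#'
#' JSON of all pairwise model comparisons (paired t-tests on concordance
#' and log-rank p) and any supplied correlations.
#'
#' @param results data.frame from [runExperiment()].
#' @param path Output file.
#' @param correlations Optional named list of [correlateMetrics()] results.
#' @return Invisibly, `path`.
#' @export
writeBenchmarkReportJSON <- function(results, path, correlations = NULL) {
  fams <- unique(results$model)
  pairs <- if (length(fams) >= 2) utils::combn(fams, 2, simplify = FALSE) else list()
  tests <- lapply(pairs, function(pr) {
    wide <- merge(results[results$model == pr[1], c("dataset", "fold", "cindex")],
                  results[results$model == pr[2], c("dataset", "fold", "cindex")],
                  by = c("dataset", "fold"), suffixes = c(".a", ".b"))
    tt <- tryCatch(pairedTTest(wide$cindex.a, wide$cindex.b),
                   error = function(e) list(error = conditionMessage(e)))
    c(list(model_a = pr[1], model_b = pr[2], metric = "cindex"), tt)
  })
  jsonlite::write_json(list(paired_tests = tests, correlations = correlations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
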