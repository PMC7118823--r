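test_that("the experiment grid emits one row per (dataset, model, fold)", {
  cohorts <- list(A = makeToyCohort(n = 50, nGenes = 20, seed = 101),
                  B = makeToyCohort(n = 50, nGenes = 20, seed = 102))
  res <- suppressMessages(runExperiment(
    cohorts, families = c("coxnnet", "deepsurv"), nSplits = 2,
    nShuffles = 20, specArgs = list(maxEpochs = 25L, hiddenSizes = 4L),
    seed = 5))
  expect_identical(nrow(res), 2L * 2L * 2L)
  expect_identical(anyDuplicated(res[, c("dataset", "model", "fold")]), 0L)
  expect_true(all(res$cindex >= 0 & res$cindex <= 1, na.rm = TRUE))
  expect_true(all(res$logrank_p > 0 & res$logrank_p <= 1, na.rm = TRUE))
  # identical seeds give an identical table
  res2 <- suppressMessages(runExperiment(
    cohorts, families = c("coxnnet", "deepsurv"), nSplits = 2,
    nShuffles = 20, specArgs = list(maxEpochs = 25L, hiddenSizes = 4L),
    seed = 5))
  expect_identical(res, res2)
})

test_that("a null-signal dataset scores at chance", {
  nullCohort <- simulateCohort(simConfig(nSamples = 150, nGenes = 30,
                                         latentRank = 2, beta = c(0, 0),
                                         seed = 77))
  res <- suppressMessages(runExperiment(
    list(null = nullCohort), families = "coxnnet", nSplits = 3,
    nShuffles = 20, specArgs = list(maxEpochs = 40L, hiddenSizes = 4L),
    seed = 3))
  expect_equal(mean(res$cindex, na.rm = TRUE), 0.5, tolerance = 0.05)
})

test_that("paired t-test matches the closed form and its symmetries", {
  # differences (1, 2, 3): t = mean/(sd/sqrt(n)) = 2*sqrt(3)
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  res <- pairedTTest(a, b)
  expect_equal(res$t, 2 * sqrt(3))
  expect_identical(res$nPairs, 3L)
  flipped <- pairedTTest(b, a)
  expect_equal(flipped$t, -res$t)
  expect_equal(flipped$p.value, res$p.value)
  expect_error(pairedTTest(a, a), "zero-variance")
  expect_error(pairedTTest(1:2, 2:3), "at least 3")
  expect_message(pairedTTest(c(a, NA), c(b, 1)), "incomplete")
})

test_that("TMB summaries follow the upper-tail quantile convention", {
  s <- tmbSummary(1:100)
  expect_equal(unname(s["median"]), 50.5)
  expect_equal(unname(s["max"]), 100)
  expect_equal(unname(s["tail20"]), 80.2)   # linear interpolation
  expect_equal(unname(s["tail10"]), 90.1)
  expect_equal(unname(s["tail5"]), 95.05)
  expect_true(s["tail5"] >= s["tail10"] && s["tail10"] >= s["tail20"])
  cst <- tmbSummary(rep(7, 10))
  expect_true(all(cst == 7))
  expect_error(tmbSummary(c(1, -2)), "non-negative")
})

test_that("correlations match their textbook definitions", {
  x <- 1:12
  expect_equal(correlateMetrics(x, 2 * x + 1, "pearson")$rho, 1)
  expect_equal(correlateMetrics(x, exp(-x), "spearman")$rho, -1)
  set.seed(10)
  y <- rnorm(12)
  ref <- cor(x, y)
  expect_equal(correlateMetrics(x, y, "pearson")$rho, ref)
  expect_error(correlateMetrics(x, rep(1, 12)), "zero-variance")
})

test_that("TMB augmentation appends one scaled feature on the intersection", {
  cohort <- preprocessCohort(makeToyCohort(n = 30, nGenes = 20, seed = 55,
                                           tmbCoupling = 0.5))
  aug <- tmbFeatureAugment(cohort)
  expect_identical(nrow(aug), nrow(cohort) + 1L)
  tmbRow <- exprValues(aug)["TMB", ]
  expect_gte(min(tmbRow), 0); expect_lte(max(tmbRow), 1)
  # samples without TMB are dropped
  cd <- SummarizedExperiment::colData(cohort)
  cd$tmb[1:5] <- NA
  SummarizedExperiment::colData(cohort) <- cd
  expect_message(aug2 <- tmbFeatureAugment(cohort), "dropped")
  expect_identical(ncol(aug2), ncol(cohort) - 5L)
  cd$tmb <- NA_integer_
  SummarizedExperiment::colData(cohort) <- cd
  expect_error(tmbFeatureAugment(cohort), "no samples")
})

test_that("a redundant TMB feature leaves performance unchanged", {
  # TMB duplicating the dominant expression signal: with/without difference
  # in concordance stays near zero
  cohort <- preprocessCohort(makeToyCohort(n = 120, nGenes = 25, seed = 66))
  truth <- S4Vectors::metadata(cohort)$truth
  cd <- SummarizedExperiment::colData(cohort)
  cd$tmb <- as.integer(round(100 * exp(scale(truth$etaStar)[, 1])))
  SummarizedExperiment::colData(cohort) <- cd
  aug <- tmbFeatureAugment(cohort)
  tt <- survTime(cohort); ev <- survEvent(cohort)
  tr <- 1:80; te <- 81:120
  ciOf <- function(co) {
    X <- t(exprValues(co))
    spec <- tinySpec("coxnnet", seed = 7, maxEpochs = 60L)
    m <- trainModel(buildModel(spec, ncol(X)), X[tr, ], tt[tr], ev[tr])
    concordanceIndex(predictRisk(m, X[te, ])$eta, tt[te], ev[te])
  }
  expect_equal(ciOf(aug), ciOf(cohort), tolerance = 0.06)
})

test_that("result tables round-trip losslessly", {
  res <- data.frame(dataset = c("A", "A"), model = c("coxnnet", "aecox"),
                    fold = 1:2, cindex = c(0.71, 0.69),
                    logrank_p = c(0.01, 0.2), seed = c(5L, 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeResultTable(res, path)
  expect_identical(readResultTable(path), res)
})
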