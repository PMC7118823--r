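test_that("expression simulation is seeded, non-negative, low-rank", {
  cfg <- simConfig(nSamples = 60, nGenes = 80, latentRank = 2, seed = 3)
  ex1 <- simulateExpression(cfg)
  ex2 <- simulateExpression(cfg)
  expect_identical(ex1$expr, ex2$expr)
  expect_true(all(ex1$expr >= 0))
  expect_identical(dim(ex1$expr), c(80L, 60L))
  # noiseless rank-1 model: every gene is a monotone transform of the factor
  cfg1 <- simConfig(nSamples = 40, nGenes = 10, latentRank = 1,
                    beta = 1, noiseSd = 0, seed = 4)
  ex <- simulateExpression(cfg1)
  cors <- abs(cor(t(log(ex$expr)), ex$Z[1, ]))
  expect_true(all(cors > 0.999))
  # leading singular values dominate as noise vanishes
  s <- svd(log(ex$expr) - rowMeans(log(ex$expr)))$d
  expect_gt(s[1] / (s[2] + 1e-12), 1e3)
})

test_that("survival simulation respects the proportional-hazards mechanism", {
  cfg <- simConfig(nSamples = 500, nGenes = 20, latentRank = 2,
                   beta = c(1, 1), seed = 5)
  ex <- simulateExpression(cfg)
  sv <- simulateSurvival(ex$Z, cfg$beta, cfg$baselineRate,
                         censoringRate = 0.3, seed = 6)
  # censoring calibration: event fraction within +-0.1 of 70%
  expect_equal(mean(sv$event), 0.7, tolerance = 0.1)
  # no censoring requested: all events
  sv0 <- simulateSurvival(ex$Z, cfg$beta, cfg$baselineRate, 0, seed = 6)
  expect_true(all(sv0$event == 1))
  # strong signal: the true risk ranks survival well
  expect_gt(concordanceIndex(sv$etaStar, sv$time, sv$event), 0.75)
  # no signal: chance level
  svNull <- simulateSurvival(ex$Z, c(0, 0), cfg$baselineRate, 0.3, seed = 7)
  set.seed(8)
  expect_equal(concordanceIndex(runif(500), svNull$time, svNull$event), 0.5,
               tolerance = 0.05)
})

test_that("fitting the latent factors recovers the effect direction", {
  cfg <- simConfig(nSamples = 1000, nGenes = 20, latentRank = 2,
                   beta = c(1, -0.5), seed = 9)
  ex <- simulateExpression(cfg)
  sv <- simulateSurvival(ex$Z, cfg$beta, cfg$baselineRate, 0.3, seed = 10)
  fit <- fitLinearCox(t(ex$Z), sv$time, sv$event)
  cosSim <- sum(fit$beta * cfg$beta) /
    sqrt(sum(fit$beta^2) * sum(cfg$beta^2))
  expect_gt(cosSim, 0.9)
})

test_that("TMB counts are integers with the requested risk coupling", {
  set.seed(11)
  eta <- rnorm(1000)
  t0 <- simulateTMB(eta, coupling = 0, seed = 1)
  expect_true(all(t0 >= 0) && all(t0 == round(t0)))
  expect_lt(abs(cor(t0, eta)), 0.1)
  tPos <- simulateTMB(eta, coupling = 0.8, seed = 1)
  expect_gt(cor(tPos, eta, method = "spearman"), 0.3)
  tNeg <- simulateTMB(eta, coupling = -0.8, seed = 1)
  expect_lt(cor(tNeg, eta, method = "spearman"), -0.3)
})

test_that("clinical covariates have the configured composition", {
  cl <- simulateClinical(10000, seed = 2)
  expect_equal(mean(cl$sex == "male"), 0.5, tolerance = 0.02)
  expect_setequal(unique(cl$stage), c("I", "II", "III", "IV"))
  expect_identical(cl, simulateClinical(10000, seed = 2))
})

test_that("simulated cohorts flow through the file readers unchanged", {
  cohort <- makeToyCohort(n = 20, nGenes = 15, seed = 13, tmbCoupling = 0.4)
  dir <- withr::local_tempdir()
  paths <- writeCohortTSV(cohort, dir)
  tmbPath <- file.path(dir, "cohort_tmb.tsv")
  back <- SurvCohort(readExpressionTSV(paths[["expression"]]),
                     readClinicalTSV(paths[["clinical"]]),
                     tmb = readTMBTSV(tmbPath))
  expect_equal(exprValues(back), exprValues(cohort))
  expect_identical(tmbCounts(back), unname(tmbCounts(cohort)))
})

test_that("a strong-signal cohort beats a null cohort end to end", {
  gaps <- vapply(1:5, function(s) {
    run <- function(beta) {
      co <- preprocessCohort(simulateCohort(
        simConfig(nSamples = 120, nGenes = 30, latentRank = 2, beta = beta,
                  seed = 700 + s)))
      X <- t(exprValues(co)); tt <- survTime(co); ev <- survEvent(co)
      tr <- 1:80; te <- 81:120
      spec <- tinySpec("coxnnet", seed = s, maxEpochs = 100L)
      m <- trainModel(buildModel(spec, ncol(X)), X[tr, ], tt[tr], ev[tr])
      concordanceIndex(predictRisk(m, X[te, ])$eta, tt[te], ev[te])
    }
    run(c(1.8, 1.8)) - run(c(0, 0))
  }, numeric(1))
  expect_gte(median(gaps), 0.15)
})
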