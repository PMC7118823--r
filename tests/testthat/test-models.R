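test_that("architecture invariants are enforced", {
  expect_error(archSpec("coxnnet", hiddenSizes = c(10L, 10L)), "single hidden")
  expect_s4_class(archSpec("deepsurv", hiddenSizes = c(40L, 40L)), "ArchSpec")
  expect_error(archSpec("deepsurv", hiddenSizes = c(40L, 30L)), "one width")
  expect_error(archSpec("deepsurv", hiddenSizes = rep(8L, 5)), "1-4")
  expect_error(archSpec("aecox", hiddenSizes = rep(8L, 5)), "0, 2, 4, 6 or 8")
  expect_error(archSpec("aecox", reconWeight = 1.5), "\\[0, 1\\]")
  expect_error(archSpec("coxnnet", dropout = 1), "dropout")
})

test_that("aecox encoder and decoder widths mirror around the code", {
  spec <- archSpec("aecox", hiddenSizes = c(64L, 32L, 24L, 20L), codeSize = 16L)
  m <- buildModel(spec, 100)
  encOut <- vapply(m@weights$enc, function(l) nrow(l$W), integer(1))
  decOut <- vapply(m@weights$dec, function(l) nrow(l$W), integer(1))
  expect_identical(encOut, c(64L, 32L, 24L, 20L))
  expect_identical(decOut, rev(encOut))
  expect_identical(nrow(m@weights$code$W), 16L)     # code width
  expect_identical(ncol(m@weights$head$W), 16L)     # Cox head reads the code
  expect_identical(nrow(m@weights$out$W), 100L)     # reconstruction width
})

test_that("losses reduce to their components at boundary weights", {
  set.seed(2)
  eta <- rnorm(6); tt <- rexp(6); ev <- c(1, 1, 0, 1, 0, 1)
  expect_equal(coxLoss(eta, tt, ev, lambda = 0), coxNegLogLik(eta, tt, ev))
  # penalty term is exactly linear in lambda for frozen weights
  w <- list(layers = list(list(W = matrix(1:4, 2), b = c(0, 0))),
            head = list(W = matrix(c(1, -1), 1), b = 0))
  sumsq <- sum((1:4)^2) + 2
  expect_equal(coxLoss(eta, tt, ev, lambda = 0.3, weights = w),
               coxNegLogLik(eta, tt, ev) + 0.3 * sumsq)
  X <- matrix(rnorm(12), 6, 2); Xh <- X + 0.1
  expect_equal(aecoxLoss(X, Xh, eta, tt, ev, lambda1 = 1), mean((X - Xh)^2))
  expect_equal(aecoxLoss(X, Xh, eta, tt, ev, lambda1 = 0),
               coxNegLogLik(eta, tt, ev))
  expect_equal(aecoxLoss(X, Xh, eta, tt, ev, 0.4, lambda2 = 0.2, lambda3 = 0.1,
                         weights = w),
               0.4 * mean((X - Xh)^2) + 0.6 * coxNegLogLik(eta, tt, ev) +
                 0.2 * (sum(abs(1:4)) + 2) + 0.1 * sumsq)
  expect_error(aecoxLoss(X, Xh, eta, tt, ev, lambda1 = 2), "\\[0, 1\\]")
})

test_that("backpropagation matches numerical differentiation for every family", {
  set.seed(9)
  n <- 10; p <- 5
  X <- matrix(runif(n * p), n, p)
  tt <- rexp(n); ev <- rbinom(n, 1, 0.8); ev[1] <- 1
  specs <- list(
    archSpec("coxnnet", hiddenSizes = 6L, l2 = 0.01, seed = 3),
    archSpec("deepsurv", hiddenSizes = c(5L, 5L), activation = "selu",
             l2 = 0.01, seed = 3),
    archSpec("aecox", hiddenSizes = 5L, codeSize = 3L, reconWeight = 0.4,
             l1 = 0.02, l2 = 0.01, seed = 3))
  for (spec in specs) {
    m <- buildModel(spec, p)
    lg <- SurvNN:::.lossAndGrad(m, X, tt, ev, training = FALSE)
    ana <- flattenWeights(lg$grads)
    flat <- flattenWeights(m@weights)
    idx <- sample(length(flat), 10)
    for (i in idx) {
      h <- 1e-6
      pert <- flat; pert[i] <- pert[i] + h
      j <- 0
      m2 <- m
      m2@weights <- rapply(m@weights, function(x) {
        k <- length(x); out <- pert[(j + 1):(j + k)]; j <<- j + k
        if (!is.null(dim(x))) array(out, dim(x)) else as.numeric(out)
      }, how = "replace")
      num <- (SurvNN:::.lossAndGrad(m2, X, tt, ev, training = FALSE)$loss -
                lg$loss) / h
      expect_equal(unname(ana[i]), num, tolerance = 1e-4,
                   label = paste(spec@family, "grad", i))
    }
  }
})

test_that("training is deterministic and the loss trends down", {
  cohort <- preprocessCohort(makeToyCohort(n = 60, nGenes = 30, seed = 21))
  X <- t(exprValues(cohort)); tt <- survTime(cohort); ev <- survEvent(cohort)
  spec <- tinySpec("coxnnet", seed = 5, learningRate = 0.005)
  m1 <- trainModel(buildModel(spec, ncol(X)), X, tt, ev)
  m2 <- trainModel(buildModel(spec, ncol(X)), X, tt, ev)
  expect_identical(flattenWeights(m1@weights), flattenWeights(m2@weights))
  loss <- m1@trace$loss
  expect_lt(tail(loss, 1), loss[1])
  # near-monotone descent at this step size
  expect_lt(mean(diff(loss) > 0), 0.15)
})

test_that("the linear-degenerate network recovers the classical Cox fit", {
  set.seed(13)
  n <- 40; K <- 2
  X <- matrix(rnorm(n * K), n, K)
  sv <- simulateSurvival(t(X), c(0.9, -0.6), 0.05, 0.2, seed = 3)
  ref <- fitLinearCox(X, sv$time, sv$event)
  spec <- archSpec("coxnnet", hiddenSizes = integer(), activation = "identity",
                   dropout = 0, l2 = 0, learningRate = 0.05,
                   maxEpochs = 1500L, seed = 2)
  m <- trainModel(buildModel(spec, K), X, sv$time, sv$event)
  expect_equal(unname(drop(m@weights$head$W)), unname(ref$beta),
               tolerance = 1e-2)
})

test_that("prediction is deterministic with theta = exp(eta), latent dims are exposed", {
  cohort <- preprocessCohort(makeToyCohort(n = 40, nGenes = 25, seed = 8))
  X <- t(exprValues(cohort))
  for (fam in c("coxnnet", "deepsurv", "aecox")) {
    spec <- tinySpec(fam, seed = 4, dropout = 0.3, maxEpochs = 10L)
    m <- trainModel(buildModel(spec, ncol(X)), X, survTime(cohort),
                    survEvent(cohort))
    r1 <- predictRisk(m, X); r2 <- predictRisk(m, X)
    expect_identical(r1$eta, r2$eta)           # dropout off at inference
    expect_equal(r1$theta, exp(r1$eta))
    expect_true(all(diff(r1$theta[order(r1$eta)]) >= 0))
    emb <- extractLatent(m, X)
    expect_identical(ncol(emb), if (fam == "aecox") 4L else 8L)
    expect_identical(nrow(emb), nrow(X))
  }
  expect_error(predictRisk(m, X[, 1:3]), "feature count")
})

test_that("an untrained zero-signal model scores at chance", {
  set.seed(55)
  X <- matrix(runif(600), 60, 10)
  m <- buildModel(tinySpec("coxnnet", seed = 1), 10)
  # squash initial weights so eta is constant
  m@weights$head$W[] <- 0
  r <- predictRisk(m, X)
  expect_equal(concordanceIndex(r$eta + seq_along(r$eta) * 1e-15,
                                rexp(60), rbinom(60, 1, 0.9)),
               0.5, tolerance = 0.1)
})

test_that("no leakage: permuted outcomes give chance-level held-out concordance", {
  cohort <- preprocessCohort(makeToyCohort(n = 120, nGenes = 40, seed = 77))
  X <- t(exprValues(cohort))
  cis <- vapply(1:3, function(r) {
    set.seed(42 + r)
    perm <- sample(nrow(X))
    tt <- survTime(cohort)[perm]; ev <- survEvent(cohort)[perm]
    tr <- 1:80; te <- 81:120
    spec <- tinySpec("coxnnet", seed = 9, maxEpochs = 120L)
    m <- trainModel(buildModel(spec, ncol(X)), X[tr, ], tt[tr], ev[tr])
    concordanceIndex(predictRisk(m, X[te, ])$eta, tt[te], ev[te])
  }, numeric(1))
  expect_gte(mean(cis), 0.43)
  expect_lte(mean(cis), 0.57)
})

test_that("checkpoints round-trip through text files", {
  cohort <- preprocessCohort(makeToyCohort(n = 30, nGenes = 20, seed = 3))
  X <- t(exprValues(cohort))
  spec <- tinySpec("aecox", seed = 6, maxEpochs = 15L)
  m <- trainModel(buildModel(spec, ncol(X)), X, survTime(cohort),
                  survEvent(cohort))
  base <- withr::local_tempfile()
  saveModelCheckpoint(m, base)
  back <- loadModelCheckpoint(base)
  expect_equal(flattenWeights(back@weights), flattenWeights(m@weights),
               tolerance = 1e-12)
  expect_equal(predictRisk(back, X)$eta, predictRisk(m, X)$eta,
               tolerance = 1e-10)
})
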