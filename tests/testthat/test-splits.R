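test_that("balance score is zero for identical partitions, additive by component", {
  cohort <- makeToyCohort(n = 30, nGenes = 12, seed = 4)
  # three partitions built from three identical copies of the same block
  cd <- SummarizedExperiment::colData(cohort)
  cd$os_months <- rep(cd$os_months[1:10], 3)
  cd$event <- rep(cd$event[1:10], 3)
  cd$sex <- rep(cd$sex[1:10], 3)
  cd$stage <- rep(cd$stage[1:10], 3)
  SummarizedExperiment::colData(cohort) <- cd
  sp <- new("CohortSplit", train = 1:10, validation = 11:20, test = 21:30,
            balanceScore = NA_real_, componentScores = numeric())
  scored <- scoreSplit(sp, cohort)
  expect_equal(scored@balanceScore, 0)
  expect_equal(unname(scored@componentScores), rep(0, 5))

  # perturb only the deceased fraction: the score is that component alone
  cd$event[1:10] <- 1L
  cd$event[11:30] <- 0L
  cd$os_months <- rep(cd$os_months[1:10], 3)
  SummarizedExperiment::colData(cohort) <- cd
  scored2 <- scoreSplit(sp, cohort)
  expect_equal(scored2@balanceScore,
               unname(scored2@componentScores["deceased_fraction"]))
  expect_gt(scored2@balanceScore, 0)
})

test_that("balance score matches a hand-computed five-term sum", {
  # 12-patient toy cohort, partitions of 6/3/3
  expr <- matrix(1:24, 2, 12,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:12)))
  clin <- data.frame(
    sample_id = paste0("s", 1:12),
    os_months = c(10, 20, 30, 40, 50, 60, 15, 25, 35, 12, 48, 66),
    event = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 1, 0),
    sex = c("male", "male", "female", "female", "male", "female",
            "male", "female", "male", "female", "male", "male"),
    stage = c("I", "II", "I", "III", "II", "I",
              "II", "I", "III", "I", "II", "II"))
  cohort <- SurvCohort(expr, clin)
  sp <- new("CohortSplit", train = 1:6, validation = 7:9, test = 10:12,
            balanceScore = NA_real_, componentScores = numeric())
  scored <- scoreSplit(sp, cohort)
  # spreadsheet-style enumeration of the five components
  parts <- list(1:6, 7:9, 10:12)
  f <- function(g) sd(sapply(parts, g))
  expected <- f(function(i) mean(clin$sex[i] == "male")) +
    f(function(i) sd(clin$os_months[i])) +
    f(function(i) mean(clin$os_months[i])) +
    f(function(i) mean(clin$event[i])) +
    sum(sapply(c("I", "II", "III"), function(l)
      f(function(i) mean(clin$stage[i] == l))))
  expect_equal(scored@balanceScore, expected)
})

test_that("split selection is seeded, sorted, correctly sized, and optimal", {
  cohort <- makeToyCohort(n = 47, nGenes = 15, seed = 6)
  splits <- selectBalancedSplits(cohort, nShuffles = 50, nKeep = 5, seed = 11)
  expect_length(splits, 5)
  scores <- vapply(splits, function(s) s@balanceScore, numeric(1))
  expect_true(!is.unsorted(scores))
  for (s in splits) {
    expect_identical(length(s@train), as.integer(round(0.6 * 47)))
    expect_identical(length(s@validation), as.integer(round(0.2 * 47)))
    expect_identical(sort(c(s@train, s@validation, s@test)), 1:47)
  }
  # deterministic given the seed
  again <- selectBalancedSplits(cohort, nShuffles = 50, nKeep = 5, seed = 11)
  expect_identical(lapply(splits, function(s) s@train),
                   lapply(again, function(s) s@train))
  # brute-force re-scoring of the same seeded shuffle stream
  set.seed(11)
  oracle <- replicate(50, {
    s <- scoreSplit(SurvNN:::.randomSplit(47), cohort)
    s@balanceScore
  })
  expect_equal(scores[1], min(oracle), tolerance = 1e-12)
  expect_equal(scores, sort(oracle)[1:5], tolerance = 1e-12)
  # n_shuffles = n_keep = 1: the single shuffle comes back regardless of score
  one <- selectBalancedSplits(cohort, nShuffles = 1, nKeep = 1, seed = 3)
  expect_length(one, 1)
})

test_that("splits survive a JSON round trip", {
  cohort <- makeToyCohort(n = 25, nGenes = 10, seed = 9)
  splits <- selectBalancedSplits(cohort, nShuffles = 10, nKeep = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  writeSplitsJSON(splits, cohort, path)
  back <- readSplitsJSON(path, cohort)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]@train, splits[[i]]@train)
    expect_identical(back[[i]]@test, splits[[i]]@test)
    expect_equal(back[[i]]@balanceScore, splits[[i]]@balanceScore)
  }
})
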