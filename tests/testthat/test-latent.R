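blobs <- function(centers, nPer, sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(nPer * ncol(centers), sd = sd), nPer) +
      matrix(centers[i, ], nPer, ncol(centers), byrow = TRUE)))
}

test_that("PAM separates well-separated clouds and ties break by index", {
  emb <- blobs(rbind(c(0, 0), c(10, 10)), nPer = 10, seed = 2)
  fit <- pamCluster(emb, 2)
  expect_identical(length(unique(fit$labels[1:10])), 1L)
  expect_identical(length(unique(fit$labels[11:20])), 1L)
  expect_true(fit$labels[1] != fit$labels[11])
  expect_true(all(fit$medoids %in% seq_len(20)))
  # duplicated points: deterministic result, medoid at the lowest index
  dup <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  fitDup <- pamCluster(dup, 2, exhaustive = TRUE)
  expect_identical(fitDup$medoids, c(1L, 4L))
  expect_error(pamCluster(emb, 1), "k must lie")
  expect_error(pamCluster(emb, 20), "k must lie")
})

test_that("the swap heuristic attains the exhaustive-medoid optimum for small n", {
  set.seed(14)
  for (rep in 1:5) {
    emb <- matrix(rnorm(16), 8, 2)
    for (k in 2:3) {
      heur <- pamCluster(emb, k)
      brute <- pamCluster(emb, k, exhaustive = TRUE)
      expect_equal(heur$objective, brute$objective, tolerance = 1e-10,
                   label = sprintf("rep %d k %d", rep, k))
    }
  }
})

test_that("silhouette-based selection finds three separated blobs", {
  emb <- blobs(rbind(c(0, 0), c(8, 0), c(4, 7)), nPer = 12, sd = 0.3, seed = 5)
  sel <- selectKBySilhouette(emb)
  expect_identical(sel$k, 3L)
  expect_gt(sel$assignment$avgSilhouette, 0.8)
  expect_identical(names(sel$silhouettes), as.character(2:10))
  # silhouette approaches 1 as separation grows
  embFar <- blobs(rbind(c(0, 0), c(100, 0), c(50, 90)), nPer = 12,
                  sd = 0.3, seed = 5)
  expect_gt(selectKBySilhouette(embFar)$assignment$avgSilhouette,
            sel$assignment$avgSilhouette)
  # the k ceiling drops to n - 1 for tiny inputs
  sel5 <- selectKBySilhouette(matrix(rnorm(10), 5, 2))
  expect_lte(sel5$k, 4L)
  expect_error(selectKBySilhouette(matrix(1:4, 2, 2)), "at least 3")
})

test_that("cluster survival test reduces to the grouped log-rank", {
  tt <- c(1, 2, 3, 4); ev <- rep(1, 4)
  asg <- structure(list(labels = c(1L, 1L, 2L, 2L), medoids = c(1L, 3L),
                        k = 2L, objective = 0, avgSilhouette = 1),
                   class = "clusterAssignment")
  res <- clusterSurvivalTest(asg, tt, ev)
  expect_equal(res$statistic, 2.882353, tolerance = 1e-6)
  # identical survival in both clusters: p = 1
  resNull <- clusterSurvivalTest(c(1, 2, 1, 2), c(3, 3, 7, 7), rep(1, 4))
  expect_equal(resNull$p.value, 1)
  # label permutation leaves the statistic unchanged
  resPerm <- clusterSurvivalTest(3 - asg$labels, tt, ev)
  expect_equal(resPerm$statistic, res$statistic)
  # degenerate subset: every evaluated sample in one cluster
  expect_error(clusterSurvivalTest(asg, tt, ev, subset = 1:2), "one cluster")
})

test_that("embeddings round-trip through TSV", {
  emb <- matrix(rnorm(12), 4, 3,
                dimnames = list(paste0("s", 1:4), paste0("d", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEmbeddingTSV(emb, path)
  back <- readEmbeddingTSV(path)
  expect_equal(unname(back), unname(emb), tolerance = 1e-10)
  expect_identical(rownames(back), rownames(emb))
})

test_that("learned latent space stratifies survival better than raw features", {
  # cohorts with two latent survival subgroups; compare the log-rank p of
  # clusters on the trained aecox code against clusters on raw features
  pLatent <- numeric(5); pRaw <- numeric(5)
  for (i in 1:5) {
    cohort <- preprocessCohort(makeToyCohort(n = 100, nGenes = 30,
                                             seed = 400 + i,
                                             beta = c(1.8, 1.8)))
    X <- t(exprValues(cohort)); tt <- survTime(cohort); ev <- survEvent(cohort)
    tr <- 1:70; te <- 71:100
    spec <- tinySpec("aecox", seed = i, maxEpochs = 150L, reconWeight = 0.3)
    m <- trainModel(buildModel(spec, ncol(X)), X[tr, ], tt[tr], ev[tr])
    emb <- extractLatent(m, X)
    kl <- pamCluster(emb, 2)
    kr <- pamCluster(X, 2)
    pLatent[i] <- tryCatch(
      clusterSurvivalTest(kl, tt, ev, subset = te)$p.value,
      error = function(e) 1)
    pRaw[i] <- tryCatch(
      clusterSurvivalTest(kr, tt, ev, subset = te)$p.value,
      error = function(e) 1)
  }
  expect_lt(median(pLatent), median(pRaw))
})
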