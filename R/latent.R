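#' k-medoids (PAM) clustering of a latent embedding
#'
#' Partitioning Around Medoids under Euclidean distance on the last-
#' hidden-layer (or bottleneck-code) embedding, used to inspect how well a
#' trained model separates patient subgroups in its low-dimensional
#' representation. Delegates to [cluster::pam()] (BUILD + SWAP); an
#' exhaustive mode enumerates all medoid subsets for small instances and
#' is the testing oracle for the swap heuristic.
#'
#' @param embedding Samples x d numeric matrix.
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param exhaustive If `TRUE`, minimize the objective by brute force over
#'   all `choose(n, k)` medoid sets (small n only).
#' @param nStarts Number of seeded random medoid initializations tried in
#'   addition to the BUILD phase; the best swap-converged solution is kept
#'   (the swap phase only guarantees a single-swap local optimum, and
#'   restarts make reaching the global optimum far more reliable on small
#'   instances).
#' @return A list of class `clusterAssignment` with `labels` (1..k),
#'   `medoids` (row indices), `k`, `objective` (total distance to the
#'   assigned medoid), and `avgSilhouette`.
#' @export
pamCluster <- function(embedding, k, exhaustive = FALSE, nStarts = 8) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  if (k < 2 || k > n - 1) stop("k must lie in [2, n-1]")
  dd <- stats::dist(embedding)
  D <- as.matrix(dd)
  if (exhaustive) {
    if (n > 12) stop("exhaustive mode is limited to n <= 12")
    best <- NULL; bestObj <- Inf
    for (med in utils::combn(n, k, simplify = FALSE)) {
      obj <- sum(apply(D[, med, drop = FALSE], 1, min))
      if (obj < bestObj - 1e-12) { bestObj <- obj; best <- med }
    }
    labels <- apply(D[, best, drop = FALSE], 1, which.min)
    medoids <- unlist(best)
  } else {
    old <- .seedState(); on.exit(.restoreSeed(old))
    set.seed(k * 1000L + n)
    inits <- c(list(NULL),
               lapply(seq_len(nStarts), function(i) sample(n, k)))
    bestObj <- Inf; labels <- NULL; medoids <- NULL
    for (init in inits) {
      fit <- if (is.null(init)) cluster::pam(dd, k = k)
      else cluster::pam(dd, k = k, medoids = init)
      med <- unname(fit$id.med)
      lab <- unname(fit$clustering)
      obj <- sum(D[cbind(seq_len(n), med[lab])])
      if (obj < bestObj - 1e-12) { bestObj <- obj; medoids <- med; labels <- lab }
    }
  }
  sil <- .avgSilhouette(labels, D)
  structure(list(labels = as.integer(labels), medoids = as.integer(medoids),
                 k = as.integer(k), objective = bestObj,
                 avgSilhouette = sil),
            class = "clusterAssignment")
}

# average silhouette width; singleton clusters contribute 0
.avgSilhouette <- function(labels, D) {
  sizes <- table(labels)
  if (length(sizes) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = D)
  mean(sil[, "sil_width"])
}

#' @export
print.clusterAssignment <- function(x, ...) {
  cat("PAM clustering: k =", x$k, " objective =", signif(x$objective, 6),
      " avg silhouette =", signif(x$avgSilhouette, 4), "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Select the number of clusters by average silhouette
#'
#' Runs [pamCluster()] for each k in `[kMin, min(kMax, n - 1)]` and keeps
#' the k maximizing the average silhouette width (cohesion vs separation,
#' in \[-1, 1\]).
#'
#' @param embedding Samples x d matrix.
#' @param kMin,kMax Search range (defaults 2 and 10).
#' @return A list with `k`, the winning `assignment`, and `silhouettes`
#'   (named vector over the k values tried).
#' @export
selectKBySilhouette <- function(embedding, kMin = 2, kMax = 10) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 3) stop("need at least 3 samples to choose a cluster count")
  ks <- seq(kMin, min(kMax, n - 1))
  fits <- lapply(ks, function(k) pamCluster(embedding, k))
  sils <- vapply(fits, `[[`, numeric(1), "avgSilhouette")
  names(sils) <- ks
  best <- which.max(sils)
  list(k = ks[best], assignment = fits[[best]], silhouettes = sils)
}

#' Survival separation of latent clusters
#'
#' K-group log-rank test of the cluster assignment against survival,
#' restricted to a held-out subset (the clustering itself may be fit on
#' all samples' embeddings; the test is evaluated on the testing set only).
#'
#' @param assignment A `clusterAssignment` (or a plain label vector).
#' @param time,event Survival outcomes for all samples.
#' @param subset Indices of the evaluation (testing) samples; default all.
#' @return [logrankTest()] result list.
#' @export
clusterSurvivalTest <- function(assignment, time, event,
                                subset = seq_along(time)) {
  labels <- if (inherits(assignment, "clusterAssignment"))
    assignment$labels else assignment
  .checkOutcomes(time, event, n = length(labels))
  labs <- labels[subset]
  if (length(unique(labs)) < 2)
    stop("all evaluation samples fall in one cluster: log-rank undefined")
  logrankTest(labs, time[subset], event[subset])
}

#' Write an embedding to TSV / read it back
#'
#' Tab-separated `sample_id` plus d coordinate columns.
#'
#' @param embedding Samples x d matrix with rownames.
#' @param path File path.
#' @return Invisibly `path` (writer); the matrix (reader).
#' @export
writeEmbeddingTSV <- function(embedding, path) {
  df <- data.frame(sample_id = rownames(embedding) %||%
                     paste0("S", seq_len(nrow(embedding))),
                   as.data.frame(embedding))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingTSV
#' @export
readEmbeddingTSV <- function(path) {
  df <- utils::read.delim(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a cluster report
#'
#' JSON with labels, medoids, silhouettes, and the log-rank result.
#'
#' @param assignment A `clusterAssignment`.
#' @param logrank Optional [logrankTest()] result to embed.
#' @param sampleIds Optional sample identifiers.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeClusterReportJSON <- function(assignment, path, logrank = NULL,
                                   sampleIds = NULL) {
  jsonlite::write_json(
    list(k = assignment$k,
         labels = if (is.null(sampleIds)) assignment$labels else
           as.list(stats::setNames(assignment$labels, sampleIds)),
         medoids = assignment$medoids,
         objective = assignment$objective,
         avg_silhouette = assignment$avgSilhouette,
         logrank = logrank),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
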