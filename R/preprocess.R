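#' Filter weakly expressed and low-variance genes
#'
#' Two-stage denoising filter applied before model training: first the
#' fraction `exprFraction` of genes with the lowest mean absolute
#' expression across samples is removed, then the fraction `varFraction`
#' of the *remaining* genes with the lowest variance across samples. Counts
#' are floors (`floor(fraction * G)`), ties are broken by input gene order
#' (stable), and the ordering of surviving genes is preserved.
#'
#' @param x Genes x samples numeric matrix, or a [SurvCohort-class].
#' @param exprFraction Fraction of genes removed by the expression filter
#'   (default 0.20).
#' @param varFraction Fraction of the remaining genes removed by the
#'   variance filter (default 0.10).
#' @return The filtered matrix (or cohort).
#' @export
filterGenes <- function(x, exprFraction = 0.20, varFraction = 0.10) {
  if (is(x, "SurvCohort")) {
    keep <- rownames(filterGenes(exprValues(x), exprFraction, varFraction))
    return(x[keep, ])
  }
  m <- as.matrix(x)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  if (exprFraction < 0 || exprFraction >= 1 || varFraction < 0 || varFraction >= 1)
    stop("filter fractions must lie in [0, 1)")
  dropLowest <- function(mat, stat, frac) {
    nDrop <- floor(frac * nrow(mat))
    if (nDrop == 0) return(mat)
    if (anyDuplicated(stat))
      warning("tied filter statistics broken by input gene order")
    ord <- order(stat)                       # stable: ties keep input order
    mat[-ord[seq_len(nDrop)], , drop = FALSE]
  }
  m <- dropLowest(m, rowMeans(abs(m)), exprFraction)
  m <- dropLowest(m, apply(m, 1, stats::var), varFraction)
  if (nrow(m) == 0) stop("all genes removed by filtering")
  m
}

#' Natural-log transform of expression values
#'
#' Elementwise \eqn{\log(x + 1)} rescaling of the non-negative expression
#' matrix; the model input transform applied after gene filtering.
#'
#' @param x Genes x samples non-negative matrix, or a [SurvCohort-class].
#' @return Transformed matrix (or cohort).
#' @export
logTransform <- function(x) {
  if (is(x, "SurvCohort")) {
    SummarizedExperiment::assay(x, "expr") <- logTransform(exprValues(x))
    return(x)
  }
  m <- as.matrix(x)
  if (any(m < 0)) stop("log transform requires non-negative values")
  log1p(m)
}

#' Per-gene min-max scaling
#'
#' Maps each gene (row) to \[0, 1\] by \eqn{(x - \min)/(\max - \min)}, so
#' every gene contributes to the model on an equal scale. Constant rows
#' would divide by zero; they are mapped to all-zeros with a warning.
#'
#' @param x Genes x samples matrix, or a [SurvCohort-class].
#' @return Scaled matrix (or cohort).
#' @export
minmaxScaleGenes <- function(x) {
  if (is(x, "SurvCohort")) {
    SummarizedExperiment::assay(x, "expr") <- minmaxScaleGenes(exprValues(x))
    return(x)
  }
  m <- as.matrix(x)
  if (nrow(m) == 0) stop("empty expression matrix")
  rmin <- apply(m, 1, min)
  rmax <- apply(m, 1, max)
  rng <- rmax - rmin
  if (any(rng == 0)) {
    warning(sum(rng == 0), " constant gene row(s) mapped to zeros")
    rng[rng == 0] <- 1
  }
  (m - rmin) / rng
}

#' Full preprocessing pipeline
#'
#' Applies, in order: gene filtering ([filterGenes()]), the log transform
#' ([logTransform()]), and per-gene min-max scaling ([minmaxScaleGenes()]).
#' Scaling statistics are computed on the full cohort, before any
#' train/validation/test split is drawn; this mirrors common practice for
#' per-gene range normalization but is a mild form of information sharing
#' across the eventual split (documented caveat).
#'
#' @param cohort A [SurvCohort-class] (raw, non-negative expression).
#' @inheritParams filterGenes
#' @return The preprocessed cohort, flagged `preprocessed`.
#' @export
preprocessCohort <- function(cohort, exprFraction = 0.20, varFraction = 0.10) {
  stopifnot(is(cohort, "SurvCohort"))
  if (cohort@preprocessed) {
    warning("cohort is already preprocessed; returning unchanged")
    return(cohort)
  }
  out <- filterGenes(cohort, exprFraction, varFraction)
  out@preprocessed <- TRUE   # scaled values leave the raw count scale
  SummarizedExperiment::assay(out, "expr") <-
    minmaxScaleGenes(logTransform(exprValues(out)))
  validObject(out)
  out
}
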