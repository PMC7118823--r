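#' Construct a SurvCohort
#'
#' Assembles an expression matrix and a clinical table into a
#' [SurvCohort-class]. Samples are matched by id; samples missing from
#' either input are dropped with a message. Clinical rows with missing
#' survival fields are rejected.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); non-negative normalized expression.
#' @param clinical data.frame with columns `sample_id`, `os_months`,
#'   `event`, and optionally `sex` (male/female/unknown), `stage`.
#' @param tmb Optional named numeric vector (or two-column data.frame
#'   `sample_id`, `mutation_count`) of per-sample mutation counts.
#' @return A [SurvCohort-class].
#' @export
SurvCohort <- function(expr, clinical, tmb = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene ids as rownames and sample ids as colnames")
  req <- c("sample_id", "os_months", "event")
  if (!all(req %in% colnames(clinical)))
    stop("clinical table must contain columns: ", paste(req, collapse = ", "))
  if (anyNA(clinical[, req]))
    stop("missing values in required clinical fields are not allowed")
  if (anyDuplicated(clinical$sample_id)) stop("duplicated sample ids in clinical table")

  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) == 0) stop("no samples shared between expression and clinical inputs")
  dropped <- (ncol(expr) - length(common)) + (nrow(clinical) - length(common))
  if (dropped > 0)
    message(dropped, " sample record(s) without a matching counterpart dropped")
  expr <- expr[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]

  cd <- S4Vectors::DataFrame(
    os_months = as.numeric(clinical$os_months),
    event = as.integer(clinical$event),
    sex = if ("sex" %in% colnames(clinical)) as.character(clinical$sex) else
      rep("unknown", length(common)),
    stage = if ("stage" %in% colnames(clinical)) as.character(clinical$stage) else
      rep(NA_character_, length(common)),
    row.names = common)
  if (!is.null(tmb)) {
    if (is.data.frame(tmb)) tmb <- stats::setNames(tmb$mutation_count, tmb$sample_id)
    cd$tmb <- unname(tmb[common])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr), colData = cd)
  new("SurvCohort", se, preprocessed = FALSE)
}

#' @describeIn SurvCohort Overall-survival times in months.
#' @param x A `SurvCohort`.
#' @export
survTime <- function(x) SummarizedExperiment::colData(x)$os_months

#' @describeIn SurvCohort Death indicator (1 = deceased, 0 = censored).
#' @export
survEvent <- function(x) SummarizedExperiment::colData(x)$event

#' @describeIn SurvCohort Sex labels.
#' @export
sampleSex <- function(x) SummarizedExperiment::colData(x)$sex

#' @describeIn SurvCohort Tumor stage labels.
#' @export
tumorStage <- function(x) SummarizedExperiment::colData(x)$stage

#' @describeIn SurvCohort Per-sample tumor mutation burden counts (or NULL).
#' @export
tmbCounts <- function(x) SummarizedExperiment::colData(x)$tmb

#' @describeIn SurvCohort Expression values (genes x samples).
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "expr")

setMethod("show", "SurvCohort", function(object) {
  cat("SurvCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  ev <- survEvent(object)
  cat(sprintf("  events: %d deceased / %d censored (%.1f%% censoring)\n",
              sum(ev), sum(ev == 0), 100 * mean(ev == 0)))
  cat(sprintf("  os_months: median %.1f, range %.1f-%.1f\n",
              stats::median(survTime(object)), min(survTime(object)),
              max(survTime(object))))
  if (!is.null(tmbCounts(object))) cat("  TMB counts attached\n")
  cat("  preprocessed:", object@preprocessed, "\n")
  invisible(NULL)
})

setMethod("show", "CohortSplit", function(object) {
  cat(sprintf("CohortSplit: %d train / %d validation / %d test\n",
              length(object@train), length(object@validation),
              length(object@test)))
  cat("  balance score:", signif(object@balanceScore, 5), "\n")
  invisible(NULL)
})

setMethod("show", "ArchSpec", function(object) {
  cat("ArchSpec <", object@family, ">\n", sep = "")
  cat("  hidden:", if (length(object@hiddenSizes))
    paste(object@hiddenSizes, collapse = "-") else "(none: linear)",
    " activation:", object@activation, "\n")
  if (object@family == "aecox")
    cat("  code:", object@codeSize, " lambda1:", object@reconWeight,
        " lambda2:", object@l1, " lambda3:", object@l2, "\n")
  else cat("  lambda (L2):", object@l2, "\n")
  cat("  dropout:", object@dropout, " lr:", object@learningRate,
      " maxEpochs:", object@maxEpochs, " seed:", object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "NeuralSurvModel", function(object) {
  cat("NeuralSurvModel (", object@spec@family, "), ",
      if (object@trained) "trained" else "untrained",
      ", ", object@nFeatures, " input features\n", sep = "")
  if (nrow(object@trace))
    cat("  final training loss:", signif(utils::tail(object@trace$loss, 1), 6), "\n")
  invisible(NULL)
})

#' Read a Firehose-style expression table
#'
#' Tab-separated text, first column gene ids, header row of sample ids.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
readExpressionTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values in ", path)
  m
}

#' Read a clinical annotation table
#'
#' Tab-separated text with columns `sample_id`, `os_months`, `event`, and
#' optionally `sex`, `stage`. Missing required fields are rejected.
#'
#' @param path File path.
#' @return data.frame.
#' @export
readClinicalTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "os_months", "event")
  if (!all(req %in% colnames(df)))
    stop("clinical file must contain columns: ", paste(req, collapse = ", "))
  if (anyNA(df[, req])) stop("missing values in required clinical fields")
  df
}

#' Read per-sample TMB counts
#'
#' Tab-separated text with columns `sample_id`, `mutation_count`.
#'
#' @param path File path.
#' @return Named numeric vector of mutation counts.
#' @export
readTMBTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "mutation_count") %in% colnames(df)))
    stop("TMB file must contain columns sample_id, mutation_count")
  if (any(df$mutation_count < 0)) stop("mutation counts must be non-negative")
  stats::setNames(df$mutation_count, df$sample_id)
}

#' Write a cohort to the tab-separated exchange formats
#'
#' Writes the expression matrix (gene id first column, sample-id header),
#' the clinical table, and, when present, the TMB table, in the formats the
#' readers accept.
#'
#' @param cohort A [SurvCohort-class].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
writeCohortTSV <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_expression.tsv"))
  cp <- file.path(dir, paste0(prefix, "_clinical.tsv"))
  em <- data.frame(gene_id = rownames(cohort), exprValues(cohort),
                   check.names = FALSE)
  utils::write.table(em, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- data.frame(sample_id = colnames(cohort), os_months = survTime(cohort),
                   event = survEvent(cohort), sex = sampleSex(cohort),
                   stage = tumorStage(cohort))
  utils::write.table(cl, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(expression = ep, clinical = cp)
  if (!is.null(tmbCounts(cohort))) {
    tp <- file.path(dir, paste0(prefix, "_tmb.tsv"))
    utils::write.table(
      data.frame(sample_id = colnames(cohort), mutation_count = tmbCounts(cohort)),
      tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tmb = tp)
  }
  invisible(paths)
}
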