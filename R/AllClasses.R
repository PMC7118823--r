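#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' SurvCohort: an expression cohort with survival annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' non-negative normalized expression (genes in rows, samples in columns)
#' and whose `colData` carries, per sample, overall-survival time in months
#' (`os_months`), the death indicator (`event`, 1 = deceased, 0 = censored),
#' and optionally `sex`, tumor `stage`, and a tumor mutation burden count
#' (`tmb`).
#'
#' @slot preprocessed logical scalar; set by [preprocessCohort()] once the
#'   filter/log/min-max pipeline has been applied (scaled values are no
#'   longer on the raw non-negative count scale).
#' @export
setClass("SurvCohort",
         contains = "SummarizedExperiment",
         representation(preprocessed = "logical"),
         prototype(preprocessed = FALSE))

setValidity("SurvCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msgs <- character()
  if (!all(c("os_months", "event") %in% colnames(cd)))
    msgs <- c(msgs, "colData must contain 'os_months' and 'event'")
  else {
    if (any(cd$os_months < 0, na.rm = TRUE))
      msgs <- c(msgs, "os_months must be non-negative")
    if (!all(cd$event %in% c(0, 1)))
      msgs <- c(msgs, "event must be 0 or 1")
  }
  if (length(SummarizedExperiment::assays(object)) >= 1) {
    a <- SummarizedExperiment::assay(object, 1)
    if (!object@preprocessed && any(a < 0))
      msgs <- c(msgs, "expression values must be non-negative")
  }
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' CohortSplit: one balanced train/validation/test partition
#'
#' Disjoint sample-index sets covering a cohort exactly once, in
#' approximately 60/20/20 proportion (train = round(0.6 n), validation =
#' round(0.2 n), test = the remainder), together with the five-component
#' confound-balance score assigned by [scoreSplit()].
#'
#' @slot train,validation,test integer sample indices.
#' @slot balanceScore sum of the five component standard deviations.
#' @slot componentScores named numeric of length 5: `sex_ratio`, `os_sd`,
#'   `os_mean`, `deceased_fraction`, `stage_composition`.
#' @export
setClass("CohortSplit",
         representation(train = "integer", validation = "integer",
                        test = "integer", balanceScore = "numeric",
                        componentScores = "numeric"))

setValidity("CohortSplit", function(object) {
  idx <- c(object@train, object@validation, object@test)
  msgs <- character()
  if (anyDuplicated(idx)) msgs <- c(msgs, "partitions must be disjoint")
  if (length(object@train) == 0 || length(object@validation) == 0 ||
      length(object@test) == 0)
    msgs <- c(msgs, "every partition must be non-empty")
  if (length(object@componentScores) &&
      length(object@componentScores) != 5L)
    msgs <- c(msgs, "componentScores must have five components")
  if (length(msgs)) msgs else TRUE
})

#' ArchSpec: a neural survival architecture configuration
#'
#' Describes one of the three model families and its hyperparameters:
#' \describe{
#'   \item{coxnnet}{single hidden tanh layer feeding a Cox regression head.}
#'   \item{deepsurv}{1--4 hidden layers of one common width (ReLU or SELU)
#'     feeding a Cox regression head.}
#'   \item{aecox}{autoencoder with mirror-symmetric encoder/decoder hidden
#'     layers (ReLU + dropout), a linear bottleneck code (default width 16)
#'     whose tanh feeds the Cox head; trained on the weighted sum of
#'     reconstruction MSE and the Cox partial likelihood.}
#' }
#' For the linear special case (classical Cox regression trained by
#' gradient descent) `hiddenSizes` may be empty for coxnnet/deepsurv.
#'
#' @slot family one of `"coxnnet"`, `"deepsurv"`, `"aecox"`.
#' @slot hiddenSizes integer widths of the hidden layers (for aecox: the
#'   encoder half, mirrored in the decoder; total hidden-layer count is
#'   `2 * length(hiddenSizes)` and must lie in \{0, 2, 4, 6, 8\}).
#' @slot codeSize bottleneck width (aecox only), default 16.
#' @slot activation `"tanh"`, `"relu"`, `"selu"`, or `"identity"`.
#' @slot dropout dropout rate in \[0, 1).
#' @slot l2 ridge weight \eqn{\lambda} (coxnnet/deepsurv) or \eqn{\lambda_3}
#'   (aecox).
#' @slot reconWeight reconstruction weight \eqn{\lambda_1 \in [0,1]}
#'   (aecox).
#' @slot l1 lasso weight \eqn{\lambda_2 \ge 0} (aecox).
#' @slot learningRate Adam learning rate.
#' @slot maxEpochs training epoch budget.
#' @slot seed integer seed controlling initialization and dropout.
#' @export
setClass("ArchSpec",
         representation(family = "character", hiddenSizes = "integer",
                        codeSize = "integer", activation = "character",
                        dropout = "numeric", l2 = "numeric",
                        reconWeight = "numeric", l1 = "numeric",
                        learningRate = "numeric", maxEpochs = "integer",
                        seed = "integer"))

setValidity("ArchSpec", function(object) {
  msgs <- character()
  fam <- object@family
  if (!fam %in% c("coxnnet", "deepsurv", "aecox"))
    msgs <- c(msgs, "family must be coxnnet, deepsurv or aecox")
  if (!object@activation %in% c("tanh", "relu", "selu", "identity"))
    msgs <- c(msgs, "unknown activation")
  hs <- object@hiddenSizes
  if (fam == "coxnnet" && length(hs) > 1)
    msgs <- c(msgs, "coxnnet has a single hidden layer")
  if (fam == "deepsurv" && length(hs) > 0 && length(unique(hs)) != 1)
    msgs <- c(msgs, "deepsurv hidden layers must share one width")
  if (fam == "deepsurv" && length(hs) > 4)
    msgs <- c(msgs, "deepsurv supports 1-4 hidden layers")
  if (fam == "aecox" && !(2 * length(hs)) %in% c(0, 2, 4, 6, 8))
    msgs <- c(msgs, "aecox total hidden-layer count must be 0, 2, 4, 6 or 8")
  if (any(hs < 1)) msgs <- c(msgs, "hidden sizes must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must be in [0, 1)")
  if (object@reconWeight < 0 || object@reconWeight > 1)
    msgs <- c(msgs, "reconWeight (lambda1) must be in [0, 1]")
  if (object@l1 < 0 || object@l2 < 0)
    msgs <- c(msgs, "penalty weights must be non-negative")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be positive")
  if (object@maxEpochs < 1) msgs <- c(msgs, "maxEpochs must be at least 1")
  if (length(msgs)) msgs else TRUE
})

#' NeuralSurvModel: a (possibly trained) neural Cox model
#'
#' Holds the architecture specification, the weight matrices, and the
#' per-epoch training trace. Prediction and latent extraction are
#' deterministic given the weights (dropout is disabled at inference).
#'
#' @slot spec the [ArchSpec-class].
#' @slot weights list of layer weight/bias matrices.
#' @slot nFeatures input dimensionality the model was built for.
#' @slot trained logical.
#' @slot trace data.frame of per-epoch loss (and validation concordance
#'   when a validation set was supplied).
#' @export
setClass("NeuralSurvModel",
         representation(spec = "ArchSpec", weights = "list",
                        nFeatures = "integer", trained = "logical",
                        trace = "data.frame"),
         prototype(trained = FALSE, trace = data.frame()))
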