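#' Define a hyperparameter search space
#'
#' A space is a named list of dimensions, each `list(low, high, scale,
#' type)` with `scale` in \{"linear", "log"\} and `type` in \{"real",
#' "integer", "categorical"\}. Categorical dimensions select by index into
#' `low:high` (after rounding); values for them are supplied through
#' `values`.
#'
#' @param ... Named dimension definitions, each a list with elements
#'   `low`, `high`, and optionally `scale` (default "linear"), `type`
#'   (default "real"), `values` (categorical choices).
#' @return An object of class `hyperParamSpace`.
#' @examples
#' hyperParamSpace(l2 = list(low = 1e-4, high = 1, scale = "log"))
#' @export
hyperParamSpace <- function(...) {
  dims <- list(...)
  if (!length(dims) || is.null(names(dims)) || any(names(dims) == ""))
    stop("every dimension must be named")
  dims <- lapply(dims, function(d) {
    d$scale <- d$scale %||% "linear"
    d$type <- d$type %||% "real"
    if (!d$scale %in% c("linear", "log")) stop("scale must be linear or log")
    if (!d$type %in% c("real", "integer", "categorical"))
      stop("type must be real, integer or categorical")
    if (d$type == "categorical") {
      if (is.null(d$values)) stop("categorical dimension needs 'values'")
      d$low <- 1; d$high <- length(d$values)
    }
    if (!is.finite(d$low) || !is.finite(d$high) || d$low >= d$high)
      stop("bounds must be finite with low < high")
    if (d$scale == "log" && d$low <= 0) stop("log scale needs positive bounds")
    d
  })
  structure(dims, class = "hyperParamSpace")
}

#' Map unit-cube points into a search space
#'
#' Affine map for linear dimensions, exponential (geometric) map for log
#' dimensions, rounding for integer dimensions, index selection for
#' categorical ones.
#'
#' @param points `q x p` matrix in \[0, 1) (e.g. from [sobolPoints()]).
#' @param space A [hyperParamSpace()].
#' @return A list of `q` named parameter lists.
#' @export
mapToSpace <- function(points, space) {
  stopifnot(inherits(space, "hyperParamSpace"))
  points <- as.matrix(points)
  if (ncol(points) != length(space))
    stop("point dimension (", ncol(points), ") must equal the space's (",
         length(space), ")")
  apply(points, 1, function(u) {
    vals <- Map(function(x, d) {
      v <- if (d$scale == "log")
        exp(log(d$low) + x * (log(d$high) - log(d$low)))
      else d$low + x * (d$high - d$low)
      if (d$type == "real") return(v)
      idx <- min(max(round(v), ceiling(d$low)), floor(d$high))
      if (d$type == "integer") as.integer(idx) else d$values[[idx]]
    }, as.list(u), space)
    stats::setNames(vals, names(space))
  }, simplify = FALSE)
}

#' Default search spaces per model family
#'
#' coxnnet exposes only the L2 weight \eqn{\lambda} (a 1-D space, searched
#' by a 12-point line search). deepsurv and aecox expose their multi-
#' dimensional spaces (searched with the Sobol sequence, budget 100 by
#' default): layer counts 1--4 (deepsurv) and 0--4 encoder/decoder pairs
#' (aecox, i.e. total hidden layers 0/2/4/6/8), last-layer widths in
#' \[30, 50\] (deepsurv) with the aecox code fixed at 16, plus learning
#' rate, dropout, and regularization weights. Unlisted bounds (learning
#' rate, dropout, the \eqn{\lambda} ranges) are package defaults.
#'
#' @param family Model family.
#' @return A [hyperParamSpace()].
#' @export
defaultSearchSpace <- function(family = c("coxnnet", "deepsurv", "aecox")) {
  family <- match.arg(family)
  switch(family,
    coxnnet = hyperParamSpace(
      l2 = list(low = 1e-4, high = 10, scale = "log")),
    deepsurv = hyperParamSpace(
      learningRate = list(low = 1e-4, high = 1e-2, scale = "log"),
      l2 = list(low = 1e-4, high = 1, scale = "log"),
      dropout = list(low = 0, high = 0.5),
      nLayers = list(low = 1, high = 4, type = "integer"),
      hiddenSize = list(low = 30, high = 50, type = "integer")),
    aecox = hyperParamSpace(
      learningRate = list(low = 1e-4, high = 1e-2, scale = "log"),
      reconWeight = list(low = 0, high = 1),
      l2 = list(low = 1e-4, high = 1, scale = "log"),
      dropout = list(low = 0, high = 0.5),
      nLayerPairs = list(low = 0, high = 4, type = "integer")))
}

# translate a sampled parameter list into an ArchSpec
.specFromParams <- function(family, params, specArgs = list()) {
  args <- specArgs
  args$family <- family
  for (nm in names(params)) {
    val <- params[[nm]]
    if (nm == "nLayers") next
    if (nm == "hiddenSize") next
    if (nm == "nLayerPairs") next
    args[[nm]] <- val
  }
  if (family == "deepsurv" && !is.null(params$nLayers)) {
    width <- params$hiddenSize %||% 40L
    args$hiddenSizes <- rep(as.integer(width), params$nLayers)
  }
  if (family == "aecox" && !is.null(params$nLayerPairs)) {
    width <- params$hiddenSize %||% 64L
    args$hiddenSizes <- if (params$nLayerPairs == 0) integer() else
      rep(as.integer(width), params$nLayerPairs)
  }
  do.call(archSpec, args)
}

#' Hyperparameter search
#'
#' Evaluates exactly `q` candidate configurations and returns the one with
#' the best validation concordance. One-dimensional spaces (the coxnnet
#' \eqn{\lambda}) are covered by an evenly spaced line search with
#' `linePoints` points (log-spaced on log-scale dimensions); multi-
#' dimensional spaces are covered by the Sobol sequence, keeping the
#' training budget linear in `q` regardless of dimensionality.
#'
#' @param family Model family (used to build candidate [archSpec()]s).
#' @param space A [hyperParamSpace()]; default [defaultSearchSpace()].
#' @param XTrain,timeTrain,eventTrain Training data.
#' @param XVal,timeVal,eventVal Validation data (scoring set).
#' @param q Search budget for multi-dimensional spaces (default 100).
#' @param linePoints Grid size for 1-D spaces (default 12).
#' @param skip Sobol skip (default 1, dropping the all-zeros point).
#' @param specArgs Named list of fixed [archSpec()] arguments applied to
#'   every candidate (e.g. a reduced `maxEpochs`).
#' @param objective Optional function `params -> score` replacing the
#'   train-and-validate objective (higher is better); used for analytic
#'   stubs and testing.
#' @return A list of class `searchResult`: `best` (parameter list),
#'   `bestSpec` (`NULL` under a stub objective), `bestScore`, `results`
#'   (data.frame of all candidates and scores), `q`.
#' @export
searchHyperparams <- function(family, space = defaultSearchSpace(family),
                              XTrain = NULL, timeTrain = NULL, eventTrain = NULL,
                              XVal = NULL, timeVal = NULL, eventVal = NULL,
                              q = 100, linePoints = 12, skip = 1L,
                              specArgs = list(), objective = NULL) {
  stopifnot(inherits(space, "hyperParamSpace"))
  p <- length(space)
  if (p == 1L) {
    d <- space[[1]]
    grid <- if (d$scale == "log")
      exp(seq(log(d$low), log(d$high), length.out = linePoints))
    else seq(d$low, d$high, length.out = linePoints)
    candidates <- lapply(grid, function(g)
      stats::setNames(list(if (d$type == "integer") as.integer(round(g)) else g),
                      names(space)))
  } else {
    candidates <- mapToSpace(sobolPoints(q, p, skip = skip), space)
  }
  if (is.null(objective)) {
    if (is.null(XTrain) || is.null(XVal))
      stop("training and validation data are required without a stub objective")
    objective <- function(params) {
      spec <- .specFromParams(family, params, specArgs)
      model <- trainModel(buildModel(spec, ncol(XTrain)),
                          XTrain, timeTrain, eventTrain,
                          XVal, timeVal, eventVal)
      max(model@trace$valCIndex, na.rm = TRUE)
    }
    usedSpec <- TRUE
  } else usedSpec <- FALSE

  scores <- vapply(candidates, function(par) {
    tryCatch(objective(par), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("all ", length(candidates), " candidates failed to train")
  resDF <- cbind(do.call(rbind, lapply(candidates, function(cc)
    as.data.frame(lapply(cc, function(v) if (is.numeric(v)) v else as.character(v))))),
    score = scores)
  bestIdx <- which.max(scores)
  structure(list(best = candidates[[bestIdx]],
                 bestSpec = if (usedSpec)
                   .specFromParams(family, candidates[[bestIdx]], specArgs)
                 else NULL,
                 bestScore = scores[bestIdx],
                 results = resDF, q = length(candidates)),
            class = "searchResult")
}

#' @export
print.searchResult <- function(x, ...) {
  cat("Hyperparameter search:", x$q, "candidates evaluated\n")
  cat("  best score:", signif(x$bestScore, 5), "\n")
  cat("  best params:", paste(names(x$best),
                              vapply(x$best, function(v) format(v, digits = 4),
                                     character(1)),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a search report
#'
#' JSON table of all evaluated candidates and their scores.
#'
#' @param result A `searchResult`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeSearchReportJSON <- function(result, path) {
  jsonlite::write_json(list(q = result$q, best = result$best,
                            bestScore = result$bestScore,
                            candidates = result$results),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
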