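#' Create a neural survival architecture specification
#'
#' Constructor for [ArchSpec-class] with per-family defaults reflecting the
#' three architectures' published configurations: a single tanh hidden
#' layer for `coxnnet` (width drawn in \[131, 135\], default 133, epoch
#' budget 4000), equal-width ReLU/SELU layers for `deepsurv` (1--4 layers,
#' last-layer width in \[30, 50\], budget 500), and a mirror-symmetric
#' ReLU autoencoder with a width-16 linear code for `aecox` (total hidden
#' layers in \{0, 2, 4, 6, 8\}, budget 300; the Cox head reads
#' `tanh(code)`).
#'
#' `hiddenSizes` for `aecox` names the encoder half only; the decoder
#' mirrors it. An empty `hiddenSizes` with family `coxnnet` or `deepsurv`
#' gives the linear special case (classical Cox regression trained by
#' gradient descent).
#'
#' @param family `"coxnnet"`, `"deepsurv"`, or `"aecox"`.
#' @param hiddenSizes Integer vector of hidden-layer widths.
#' @param codeSize Bottleneck width (aecox).
#' @param activation Hidden activation; defaults: tanh (coxnnet), relu
#'   (deepsurv, selu available), relu (aecox).
#' @param dropout Dropout rate in \[0, 1).
#' @param l2 L2 weight: \eqn{\lambda} (coxnnet/deepsurv) or \eqn{\lambda_3}
#'   (aecox).
#' @param reconWeight \eqn{\lambda_1 \in [0,1]}, reconstruction-vs-Cox
#'   balance (aecox).
#' @param l1 \eqn{\lambda_2 \ge 0}, lasso weight (aecox; 0 gives the
#'   ridge-only regime).
#' @param learningRate Adam step size.
#' @param maxEpochs Training budget (family default if `NULL`).
#' @param seed Integer seed for initialization and dropout.
#' @return An [ArchSpec-class].
#' @examples
#' archSpec("coxnnet", hiddenSizes = 131)
#' archSpec("aecox", hiddenSizes = c(64, 32), codeSize = 16)
#' @export
archSpec <- function(family = c("coxnnet", "deepsurv", "aecox"),
                     hiddenSizes = NULL, codeSize = 16L,
                     activation = NULL, dropout = 0, l2 = 1e-4,
                     reconWeight = 0.5, l1 = 0,
                     learningRate = NULL, maxEpochs = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(hiddenSizes))
    hiddenSizes <- switch(family, coxnnet = 133L, deepsurv = c(40L, 40L),
                          aecox = 64L)
  if (is.null(activation))
    activation <- switch(family, coxnnet = "tanh", deepsurv = "relu",
                         aecox = "relu")
  if (is.null(maxEpochs))
    maxEpochs <- switch(family, coxnnet = 4000L, deepsurv = 500L, aecox = 300L)
  if (is.null(learningRate))
    learningRate <- switch(family, coxnnet = 0.01, deepsurv = 0.005,
                           aecox = 0.005)
  new("ArchSpec", family = family, hiddenSizes = as.integer(hiddenSizes),
      codeSize = as.integer(codeSize), activation = activation,
      dropout = dropout, l2 = l2, reconWeight = reconWeight, l1 = l1,
      learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
      seed = as.integer(seed))
}

#' Build an untrained model
#'
#' Instantiates the weight matrices for an architecture on a given input
#' dimensionality, with seeded fan-in-scaled Gaussian initialization. For
#' aecox the decoder layer widths mirror the encoder's.
#'
#' @param spec An [ArchSpec-class].
#' @param nFeatures Number of input features (genes).
#' @return An untrained [NeuralSurvModel-class].
#' @export
buildModel <- function(spec, nFeatures) {
  stopifnot(is(spec, "ArchSpec"))
  validObject(spec)
  nFeatures <- as.integer(nFeatures)
  if (nFeatures < 1) stop("need at least one input feature")
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(spec@seed)
  hs <- spec@hiddenSizes
  if (spec@family %in% c("coxnnet", "deepsurv")) {
    sizes <- c(nFeatures, hs)
    layers <- lapply(seq_along(hs), function(i) .newLayer(sizes[i], sizes[i + 1]))
    weights <- list(layers = layers,
                    head = .newLayer(utils::tail(sizes, 1), 1L))
  } else {
    encSizes <- c(nFeatures, hs)
    enc <- lapply(seq_along(hs), function(i) .newLayer(encSizes[i], encSizes[i + 1]))
    codeIn <- utils::tail(encSizes, 1)
    decSizes <- c(spec@codeSize, rev(hs))          # mirror of the encoder
    dec <- lapply(seq_along(hs), function(i) .newLayer(decSizes[i], decSizes[i + 1]))
    weights <- list(enc = enc,
                    code = .newLayer(codeIn, spec@codeSize),
                    dec = dec,
                    out = .newLayer(utils::tail(decSizes, 1), nFeatures),
                    head = .newLayer(spec@codeSize, 1L))
  }
  new("NeuralSurvModel", spec = spec, weights = weights,
      nFeatures = nFeatures, trained = FALSE, trace = data.frame())
}

#' Cox network loss
#'
#' The training objective shared by the coxnnet and deepsurv families:
#' negative log Cox partial likelihood of the network output plus an L2
#' penalty on the weight matrices,
#' \eqn{-\ell(\eta) + \lambda\|\Theta\|_2^2}. With \eqn{\lambda = 0} it
#' reduces exactly to [coxNegLogLik()].
#'
#' @param eta Network linear predictors for the full risk-set context.
#' @param time,event Survival outcomes.
#' @param lambda Non-negative L2 weight.
#' @param weights Optional list of weight matrices (or a
#'   [NeuralSurvModel-class]) entering the penalty; biases are excluded.
#' @return Scalar loss.
#' @export
coxLoss <- function(eta, time, event, lambda = 0, weights = NULL) {
  if (is(weights, "NeuralSurvModel")) weights <- weights@weights
  coxNegLogLik(eta, time, event) +
    (if (is.null(weights)) 0 else .penaltyValue(weights, l2 = lambda))
}

#' AECOX joint loss
#'
#' The autoencoder-with-Cox objective
#' \deqn{\lambda_1 \mathrm{MSE}(X_{in}, X_{out}) + (1-\lambda_1)(-\ell(\eta))
#'   + \lambda_2\|\Theta\|_1 + \lambda_3\|\Theta\|_2^2.}
#' \eqn{\lambda_1} balances dimensionality reduction against the survival
#' regression; \eqn{\lambda_2 = 0} gives the ridge-only regime,
#' \eqn{\lambda_3 = 0} the lasso-only regime, both positive an elastic net.
#'
#' @param Xin,Xout Input and reconstructed matrices (same shape).
#' @param eta Network linear predictors.
#' @param time,event Survival outcomes.
#' @param lambda1 Reconstruction weight in \[0, 1\].
#' @param lambda2,lambda3 L1 / L2 penalty weights.
#' @param weights Optional weight-matrix list (or model) for the penalties.
#' @return Scalar loss.
#' @export
aecoxLoss <- function(Xin, Xout, eta, time, event,
                      lambda1, lambda2 = 0, lambda3 = 0, weights = NULL) {
  if (lambda1 < 0 || lambda1 > 1) stop("lambda1 must lie in [0, 1]")
  if (!all(dim(Xin) == dim(Xout))) stop("Xin and Xout must have the same shape")
  if (is(weights, "NeuralSurvModel")) weights <- weights@weights
  mse <- mean((Xin - Xout)^2)
  cox <- if (lambda1 < 1) coxNegLogLik(eta, time, event) else 0
  lambda1 * mse + (1 - lambda1) * cox +
    (if (is.null(weights)) 0 else .penaltyValue(weights, l1 = lambda2, l2 = lambda3))
}

# loss + gradient for one (full) batch; X samples x features
.lossAndGrad <- function(model, X, time, event, training = TRUE) {
  spec <- model@spec
  w <- model@weights
  n <- nrow(X)
  if (spec@family %in% c("coxnnet", "deepsurv")) {
    fw <- .forwardChain(w, X, spec@activation, spec@dropout, training)
    loss <- coxNegLogLik(fw$eta, time, event) + .penaltyValue(w, l2 = spec@l2)
    dEta <- matrix(coxNegLogLikGrad(fw$eta, time, event), ncol = 1)
    gHead <- list(W = crossprod(dEta, fw$last), b = sum(dEta))
    dA <- dEta %*% w$head$W
    bk <- .backChain(w$layers, fw$acts, fw$masks, X, dA, spec@activation)
    grads <- list(layers = bk$grads, head = gHead)
    grads <- .addPenaltyGrad(grads, w, l2 = spec@l2)
  } else {
    fw <- .forwardAE(w, X, spec@activation, spec@dropout, training)
    l1 <- spec@l1; l2 <- spec@l2; lam1 <- spec@reconWeight
    loss <- aecoxLoss(X, fw$Xhat, fw$eta, time, event, lam1, l1, l2, w)
    # reconstruction branch
    dXhat <- lam1 * 2 * (fw$Xhat - X) / length(X)
    gOut <- list(W = crossprod(dXhat, fw$decLast), b = colSums(dXhat))
    dDec <- dXhat %*% w$out$W
    bkDec <- .backChain(w$dec, fw$decActs, fw$decMasks, fw$code, dDec,
                        spec@activation)
    # survival branch through tanh(code)
    dEta <- matrix((1 - lam1) * coxNegLogLikGrad(fw$eta, time, event), ncol = 1)
    gHead <- list(W = crossprod(dEta, fw$codeT), b = sum(dEta))
    dCodeT <- dEta %*% w$head$W
    dCode <- bkDec$dInput + dCodeT * (1 - fw$codeT^2)
    gCode <- list(W = crossprod(dCode, fw$encLast), b = colSums(dCode))
    dEnc <- dCode %*% w$code$W
    bkEnc <- .backChain(w$enc, fw$encActs, fw$encMasks, X, dEnc,
                        spec@activation)
    grads <- list(enc = bkEnc$grads, code = gCode, dec = bkDec$grads,
                  out = gOut, head = gHead)
    grads <- .addPenaltyGrad(grads, w, l1 = l1, l2 = l2)
  }
  list(loss = loss, grads = grads)
}

#' Train a neural survival model
#'
#' Full-batch Adam minimization of the family loss (the full batch keeps
#' the partial-likelihood risk sets complete) for up to `maxEpochs`
#' epochs. When a validation set is supplied, the weight snapshot with the
#' best validation concordance is retained; otherwise the final weights
#' are kept. Deterministic given the spec seed.
#'
#' @param model An untrained (or warm) [NeuralSurvModel-class].
#' @param X Training features, samples x features (preprocessed scale).
#' @param time,event Training outcomes (at least 2 events).
#' @param XVal,timeVal,eventVal Optional validation set for snapshot
#'   selection.
#' @param batchSize Optional mini-batch size. The default (`NULL`) trains
#'   full-batch; mini-batches compute risk sets within the batch, a biased
#'   approximation of the full partial likelihood (a warning is issued).
#' @param verbose Print progress every 50 epochs.
#' @return The trained model with its per-epoch `trace`.
#' @export
trainModel <- function(model, X, time, event,
                       XVal = NULL, timeVal = NULL, eventVal = NULL,
                       batchSize = NULL, verbose = FALSE) {
  stopifnot(is(model, "NeuralSurvModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@nFeatures)
    stop("feature count (", ncol(X), ") does not match the model (",
         model@nFeatures, ")")
  .checkOutcomes(time, event, n = nrow(X))
  if (sum(event) < 2) stop("training set needs at least 2 events")
  if (!is.null(batchSize))
    warning("mini-batch training computes partial-likelihood risk sets ",
            "within each batch; this is a biased approximation")
  hasVal <- !is.null(XVal)
  spec <- model@spec
  old <- .seedState(); on.exit(.restoreSeed(old))
  set.seed(spec@seed + 1L)    # dropout / shuffling stream

  state <- list(m = .adamInit(model@weights), v = .adamInit(model@weights))
  bestC <- -Inf; bestW <- model@weights
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      valCIndex = numeric())
  t <- 0L
  for (epoch in seq_len(spec@maxEpochs)) {
    idxList <- if (is.null(batchSize)) list(seq_len(nrow(X))) else
      split(sample.int(nrow(X)), ceiling(seq_len(nrow(X)) / batchSize))
    epochLoss <- 0
    for (idx in idxList) {
      lg <- .lossAndGrad(model, X[idx, , drop = FALSE], time[idx], event[idx])
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; try a smaller learningRate")
      t <- t + 1L
      up <- .adamStep(model@weights, lg$grads, state, spec@learningRate, t)
      model@weights <- up$weights
      state <- up$state
      epochLoss <- epochLoss + lg$loss
    }
    valC <- NA_real_
    if (hasVal) {
      valC <- concordanceIndex(predictRisk(model, XVal)$eta, timeVal, eventVal)
      if (valC > bestC) { bestC <- valC; bestW <- model@weights }
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss = epochLoss,
                                     valCIndex = valC))
    if (verbose && epoch %% 50 == 0)
      message("epoch ", epoch, " loss ", signif(epochLoss, 6),
              if (hasVal) paste0(" valC ", signif(valC, 4)) else "")
  }
  if (hasVal) model@weights <- bestW
  model@trained <- TRUE
  model@trace <- trace
  model
}

#' Predict relative risk
#'
#' Deterministic forward pass (dropout disabled) returning the linear
#' predictor \eqn{\eta} and the hazard ratio \eqn{\theta = e^\eta} per
#' sample. Only relative risks are identified; no baseline hazard is
#' estimated.
#'
#' @param model A [NeuralSurvModel-class].
#' @param X Samples x features matrix on the training feature scale.
#' @return A list with numeric vectors `eta` and `theta`.
#' @export
predictRisk <- function(model, X) {
  stopifnot(is(model, "NeuralSurvModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@nFeatures)
    stop("feature count (", ncol(X), ") does not match the model (",
         model@nFeatures, ")")
  spec <- model@spec
  eta <- if (spec@family %in% c("coxnnet", "deepsurv"))
    .forwardChain(model@weights, X, spec@activation)$eta
  else .forwardAE(model@weights, X, spec@activation)$eta
  eta <- unname(eta)
  list(eta = eta, theta = exp(eta))
}

#' Extract the latent representation
#'
#' Returns the activations of the last hidden layer (coxnnet/deepsurv) or
#' the bottleneck code (aecox) -- the low-dimensional embedding used for
#' patient stratification. For a linear model (no hidden layer) the input
#' features are returned unchanged.
#'
#' @param model A trained [NeuralSurvModel-class].
#' @param X Samples x features matrix.
#' @return Samples x d numeric matrix.
#' @export
extractLatent <- function(model, X) {
  stopifnot(is(model, "NeuralSurvModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@nFeatures)
    stop("feature count does not match the model")
  spec <- model@spec
  emb <- if (spec@family %in% c("coxnnet", "deepsurv")) {
    fw <- .forwardChain(model@weights, X, spec@activation)
    fw$last
  } else {
    .forwardAE(model@weights, X, spec@activation)$code
  }
  rownames(emb) <- rownames(X)
  emb
}

#' Save / load a model checkpoint
#'
#' The weights go to a flat tab-separated text file and the architecture
#' spec plus seed to a JSON sidecar, so checkpoints survive text-only
#' storage.
#'
#' @param model A [NeuralSurvModel-class].
#' @param path Base path; `<path>.weights.tsv` and `<path>.spec.json` are
#'   written.
#' @return Invisibly, the base path.
#' @export
saveModelCheckpoint <- function(model, path) {
  flat <- rapply(model@weights, function(x) as.numeric(x), how = "unlist")
  utils::write.table(data.frame(name = names(flat), value = flat),
                     paste0(path, ".weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sp <- model@spec
  jsonlite::write_json(
    list(family = sp@family, hiddenSizes = sp@hiddenSizes,
         codeSize = sp@codeSize, activation = sp@activation,
         dropout = sp@dropout, l2 = sp@l2, reconWeight = sp@reconWeight,
         l1 = sp@l1, learningRate = sp@learningRate,
         maxEpochs = sp@maxEpochs, seed = sp@seed,
         nFeatures = model@nFeatures, trained = model@trained),
    paste0(path, ".spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModelCheckpoint
#' @export
loadModelCheckpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".spec.json"), simplifyVector = TRUE)
  spec <- archSpec(meta$family, hiddenSizes = meta$hiddenSizes,
                   codeSize = meta$codeSize, activation = meta$activation,
                   dropout = meta$dropout, l2 = meta$l2,
                   reconWeight = meta$reconWeight, l1 = meta$l1,
                   learningRate = meta$learningRate,
                   maxEpochs = meta$maxEpochs, seed = meta$seed)
  model <- buildModel(spec, meta$nFeatures)
  flat <- utils::read.delim(paste0(path, ".weights.tsv"))
  vals <- stats::setNames(flat$value, flat$name)
  ref <- rapply(model@weights, as.numeric, how = "unlist")
  if (length(ref) != length(vals)) stop("checkpoint does not match architecture")
  # refill preserving shapes
  i <- 0L
  model@weights <- rapply(model@weights, function(x) {
    k <- length(x)
    out <- vals[(i + 1):(i + k)]
    i <<- i + k
    if (!is.null(dim(x))) array(out, dim(x)) else as.numeric(out)
  }, how = "replace")
  model@trained <- isTRUE(meta$trained)
  model
}

#' Write per-sample risk output
#'
#' Tab-separated `sample_id`, `eta`, `theta`.
#'
#' @param risk List from [predictRisk()].
#' @param sampleIds Sample identifiers.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeRiskTSV <- function(risk, sampleIds, path) {
  utils::write.table(
    data.frame(sample_id = sampleIds, eta = risk$eta, theta = risk$theta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
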