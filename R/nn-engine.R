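# Internal feed-forward engine: dense layers, manual backprop, Adam.
# Data layout: activations are samples x units; a layer holds W (out x in)
# and b (out), so Z = A %*% t(W) + b.

.SELU_LAMBDA <- 1.0507009873554805
.SELU_ALPHA <- 1.6732632423543772

.actApply <- function(z, name) {
  switch(name,
         tanh = tanh(z),
         relu = pmax(z, 0),
         selu = .SELU_LAMBDA * ifelse(z > 0, z, .SELU_ALPHA * (exp(z) - 1)),
         identity = z,
         stop("unknown activation: ", name))
}

# derivative expressed through the activation output (z not cached)
.actDeriv <- function(a, name) {
  switch(name,
         tanh = 1 - a^2,
         relu = (a > 0) * 1,
         selu = ifelse(a > 0, .SELU_LAMBDA, a + .SELU_LAMBDA * .SELU_ALPHA),
         identity = array(1, dim(a)),
         stop("unknown activation: ", name))
}

.newLayer <- function(nIn, nOut) {
  # fan-in scaled Gaussian init; caller controls the RNG seed
  list(W = matrix(stats::rnorm(nOut * nIn, sd = 1 / sqrt(nIn)), nOut, nIn),
       b = numeric(nOut))
}

.layerForward <- function(A, layer) sweep(A %*% t(layer$W), 2, layer$b, "+")

# inverted dropout mask, already scaled by 1/(1-p)
.dropMask <- function(dimA, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(prod(dimA), 1, 1 - p) / (1 - p), dimA[1], dimA[2])
}

# ---- forward passes -------------------------------------------------------

# chain of hidden layers + scalar hazard head (coxnnet / deepsurv / linear)
.forwardChain <- function(weights, X, act, dropout = 0, training = FALSE) {
  A <- X
  acts <- list()
  masks <- list()
  for (i in seq_along(weights$layers)) {
    A <- .actApply(.layerForward(A, weights$layers[[i]]), act)
    if (training && dropout > 0) {
      m <- .dropMask(dim(A), dropout)
      A <- A * m
      masks[[i]] <- m
    }
    acts[[i]] <- A
  }
  eta <- drop(.layerForward(A, weights$head))
  list(eta = eta, acts = acts, masks = masks, last = A)
}

# autoencoder with Cox head on tanh(code)
.forwardAE <- function(weights, X, act, dropout = 0, training = FALSE) {
  A <- X
  encActs <- list(); encMasks <- list()
  for (i in seq_along(weights$enc)) {
    A <- .actApply(.layerForward(A, weights$enc[[i]]), act)
    if (training && dropout > 0) {
      m <- .dropMask(dim(A), dropout)
      A <- A * m
      encMasks[[i]] <- m
    }
    encActs[[i]] <- A
  }
  code <- .layerForward(A, weights$code)            # linear bottleneck
  codeT <- tanh(code)
  eta <- drop(.layerForward(codeT, weights$head))
  D <- code
  decActs <- list(); decMasks <- list()
  for (i in seq_along(weights$dec)) {
    D <- .actApply(.layerForward(D, weights$dec[[i]]), act)
    if (training && dropout > 0) {
      m <- .dropMask(dim(D), dropout)
      D <- D * m
      decMasks[[i]] <- m
    }
    decActs[[i]] <- D
  }
  Xhat <- .layerForward(D, weights$out)
  list(eta = eta, code = code, codeT = codeT, Xhat = Xhat,
       encActs = encActs, encMasks = encMasks, encLast = A,
       decActs = decActs, decMasks = decMasks, decLast = D)
}

# ---- backward passes ------------------------------------------------------

# backprop through a list of hidden layers given dA at the top;
# returns gradients per layer and dA at the bottom (input side)
.backChain <- function(layers, acts, masks, inputs0, dA, act) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (length(masks) >= i && !is.null(masks[[i]])) dA <- dA * masks[[i]]
    Apre <- if (i == 1) inputs0 else acts[[i - 1]]
    # derivative through the activation: recover pre-dropout activation
    Araw <- if (length(masks) >= i && !is.null(masks[[i]]))
      acts[[i]] / ifelse(masks[[i]] == 0, 1, masks[[i]]) else acts[[i]]
    dZ <- dA * .actDeriv(Araw, act)
    grads[[i]] <- list(W = crossprod(dZ, Apre), b = colSums(dZ))
    dA <- dZ %*% layers[[i]]$W
  }
  list(grads = grads, dInput = dA)
}

# ---- Adam -----------------------------------------------------------------

.adamInit <- function(weights) {
  rapply(weights, function(w) array(0, dim(w) %||% length(w)), how = "replace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten/apply update over the nested weight list
.adamStep <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- Map(walk, w, g, m, v)
      return(list(w = lapply(out, `[[`, "w"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  res <- walk(weights, grads, state$m, state$v)
  list(weights = res$w, state = list(m = res$m, v = res$v))
}

# ---- penalties ------------------------------------------------------------

# weight matrices only (biases excluded), over the whole nested list
.collectW <- function(weights) {
  out <- list()
  walk <- function(x) {
    if (is.list(x) && !is.null(x$W)) out[[length(out) + 1]] <<- x$W
    else if (is.list(x)) lapply(x, walk)
    invisible(NULL)
  }
  walk(weights)
  out
}

.penaltyValue <- function(weights, l1 = 0, l2 = 0) {
  if (l1 == 0 && l2 == 0) return(0)
  Ws <- .collectW(weights)
  l1 * sum(vapply(Ws, function(w) sum(abs(w)), numeric(1))) +
    l2 * sum(vapply(Ws, function(w) sum(w^2), numeric(1)))
}

# add penalty gradient in place on a grads list shaped like weights
.addPenaltyGrad <- function(grads, weights, l1 = 0, l2 = 0) {
  if (l1 == 0 && l2 == 0) return(grads)
  walk <- function(g, w) {
    if (is.list(g) && !is.null(g$W)) {
      g$W <- g$W + 2 * l2 * w$W + l1 * sign(w$W)
      g
    } else if (is.list(g)) Map(walk, g, w)
    else g
  }
  walk(grads, weights)
}
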