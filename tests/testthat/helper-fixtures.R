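# Shared fixtures: everything is generated in code at test time.

# small simulated cohort with latent survival signal
makeToyCohort <- function(n = 40, nGenes = 30, seed = 1, beta = c(1, 1),
                          censoringRate = 0.3, tmbCoupling = 0) {
  simulateCohort(simConfig(nSamples = n, nGenes = nGenes, latentRank = 2,
                           beta = beta, censoringRate = censoringRate,
                           tmbCoupling = tmbCoupling, seed = seed))
}

# compact architecture for fast training in tests
tinySpec <- function(family, seed = 1, ...) {
  defaults <- switch(family,
    coxnnet = list(hiddenSizes = 8L, maxEpochs = 80L),
    deepsurv = list(hiddenSizes = c(8L, 8L), maxEpochs = 80L),
    aecox = list(hiddenSizes = 8L, codeSize = 4L, maxEpochs = 80L))
  args <- utils::modifyList(c(list(family = family, seed = seed), defaults),
                            list(...))
  do.call(archSpec, args)
}

# flatten a nested weight list (numeric leaves, depth-first)
flattenWeights <- function(w) rapply(w, as.numeric, how = "unlist")
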