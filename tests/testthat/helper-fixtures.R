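# Shared fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately written as naive direct evaluations,
# independent of the package's implementation paths.

toyVariantVcf <- function() {
  system.file("extdata", "toy_variants.vcf", package = "moals")
}

# two well-separated Gaussian blobs in `dims` dimensions
makeBlobs <- function(nPerBlob = 20, dims = 2, sep = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(nPerBlob * dims, 0), nPerBlob, dims),
             matrix(rnorm(nPerBlob * dims, sep), nPerBlob, dims))
  rownames(X) <- sprintf("p%02d", seq_len(2 * nPerBlob))
  list(X = X, truth = rep(1:2, each = nPerBlob))
}

smallCohort <- function(seed = 7, n = 90, nCases = 70) {
  generateCohort(simulationConfig(
    nSamples = n, nCases = nCases, nControls = n - nCases,
    nGenesExpression = 40, nGenesBurden = 12, nSignalGenes = 5,
    latentDimTrue = 2, nBlocks = 2, seed = seed))
}

tinyTrainConfig <- function(...) {
  args <- list(latentDim = 6, hidden = c(12), headHidden = c(6),
               epochs1 = 3, epochs2 = 4, epochs3 = 3, mIntervals = 4,
               batchSize = 16)
  override <- list(...)
  args[names(override)] <- override
  do.call(moalsTrainConfig, args)
}

# direct double-loop evaluation of the fuzzy membership formula
bruteForceMembership <- function(X, V, mFuzz) {
  U <- matrix(NA_real_, nrow(X), nrow(V))
  for (i in seq_len(nrow(X))) {
    di <- sqrt(colSums((t(V) - X[i, ])^2))
    for (j in seq_len(nrow(V)))
      U[i, j] <- 1 / sum((di[j] / di)^(2 / (mFuzz - 1)))
  }
  U
}

# enumerate the m + 1 monotone 0/1 label vectors of length m
enumerateMonotoneLabels <- function(m) {
  lapply(0:m, function(j) as.integer(seq_len(m) > j))
}

# naive MTLR probability of label y under scores ys (no log guard)
bruteForceMtlrProb <- function(y, ys) {
  m <- length(ys)
  Z <- sum(vapply(0:m, function(j)
    exp(sum(ys[seq_len(m) > j])), numeric(1)))
  exp(sum(y * ys)) / Z
}

# adjusted Rand index between two hard partitions
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}

expectNoDiff <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
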