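# Fuzzy k-means: membership formula against a brute-force oracle,
# centroid updates, convergence behaviour, ranking, and pathway
# enrichment with gene selection.

test_that("membership formula matches brute-force evaluation", {
  # hand example: 1-D point at 0 with centroids 1 and 2, m = 2
  U <- fuzzyMembership(matrix(0), matrix(c(1, 2)), mFuzz = 2)
  expect_equal(as.numeric(U), c(0.8, 0.2), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:100) {
    X <- matrix(rnorm(5 * 3), 5, 3)
    V <- matrix(rnorm(3 * 3), 3, 3)
    m <- runif(1, 1.3, 3)
    expectNoDiff(fuzzyMembership(X, V, m), bruteForceMembership(X, V, m),
                 1e-10)
  }
})

test_that("membership handles degenerate geometries by the documented rules", {
  # c = 1: normalization forces full membership
  U <- fuzzyMembership(matrix(rnorm(8), 4, 2), matrix(rnorm(2), 1, 2))
  expect_equal(as.numeric(U), rep(1, 4))
  # equidistant point: exact symmetry for any fuzziness
  for (m in c(1.5, 2, 4)) {
    U <- fuzzyMembership(matrix(c(0, 0), 1, 2),
                         matrix(c(-1, 1, 0, 0), 2, 2), m)
    expect_equal(as.numeric(U), c(0.5, 0.5))
  }
  # coincident point: membership split equally among coincident centroids
  U <- fuzzyMembership(matrix(c(1, 1), 1, 2),
                       rbind(c(1, 1), c(1, 1), c(5, 5)), 2)
  expect_equal(as.numeric(U), c(0.5, 0.5, 0))
})

test_that("centroid update is the weighted mean with k-means limit", {
  X <- matrix(c(-1, 1, 0, 0), 2, 2)
  U <- matrix(0.5, 2, 1)
  expect_equal(as.numeric(updateCentroids(X, U, 2)), c(0, 0))
  expect_equal(as.numeric(updateCentroids(matrix(c(3, 4), 1), matrix(1), 2)),
               c(3, 4))
  # near-crisp membership at mFuzz -> 1 approaches per-cluster means
  blobs <- makeBlobs(10, dims = 2, seed = 3)
  Ucrisp <- cbind(as.numeric(blobs$truth == 1),
                  as.numeric(blobs$truth == 2))
  V <- updateCentroids(blobs$X, Ucrisp, 1.01)
  means <- rbind(colMeans(blobs$X[blobs$truth == 1, ]),
                 colMeans(blobs$X[blobs$truth == 2, ]))
  expectNoDiff(V, means, 1e-3)
})

test_that("fit recovers planted blobs with non-increasing objective", {
  blobs <- makeBlobs(20, dims = 2, seed = 5)
  fit <- fitFuzzyKmeans(blobs$X, c = 2, seed = 1)
  expect_true(isConverged(fit))
  expect_true(all(diff(objectiveTrace(fit)) <=
                  1e-8 * (1 + abs(objectiveTrace(fit)[-1]))))
  part <- apply(membership(fit), 1, which.max)
  expect_equal(adjustedRand(part, blobs$truth), 1)
  # membership rows sum to one
  expect_lt(max(abs(rowSums(membership(fit)) - 1)), 1e-9)
  # different seeds agree up to label permutation
  fit2 <- fitFuzzyKmeans(blobs$X, c = 2, seed = 99)
  expect_equal(adjustedRand(part, apply(membership(fit2), 1, which.max)), 1)
})

test_that("loop contract: infinite tolerance returns after one iteration", {
  blobs <- makeBlobs(10, seed = 2)
  fit <- fitFuzzyKmeans(blobs$X, c = 2, tol = Inf, seed = 1)
  expect_length(objectiveTrace(fit), 1)
  expect_true(isConverged(fit))
  expect_error(fitFuzzyKmeans(blobs$X[1:3, ], c = 5, seed = 1), "fewer")
})

test_that("fit agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  blobs <- makeBlobs(25, dims = 3, seed = 8)
  fit <- fitFuzzyKmeans(blobs$X, c = 2, seed = 4)
  ref <- e1071::cmeans(blobs$X, centers = 2, m = 2)
  expect_equal(adjustedRand(apply(membership(fit), 1, which.max),
                            ref$cluster), 1)
  # objective value at the shared optimum matches closely (evaluated with
  # the same J on both solutions)
  Jref <- sum(ref$membership^2 *
                moals:::.sqDistToCentroids(blobs$X, ref$centers))
  expect_equal(min(objectiveTrace(fit)), Jref, tolerance = 1e-3)
})

test_that("gene ranking orders by cluster then score with stable ties", {
  U <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.8, 0.2))
  rownames(U) <- c("B", "C", "A")
  fit <- new("FuzzyClustering", c = 2L, mFuzz = 2, membership = U,
             centroids = matrix(0, 2, 2), objective = 1, converged = TRUE,
             seed = 1L)
  rk <- rankGenesByMembership(fit)
  expect_identical(rk$gene, c("B", "A", "C"))
  expect_equal(rk$score, c(0.9, 0.8, 0.6))
  # uniform memberships fall back to lexicographic order
  U2 <- matrix(1 / 2, 3, 2, dimnames = list(c("Z", "M", "A"), NULL))
  fit@membership <- U2
  rk2 <- rankGenesByMembership(fit)
  expect_identical(rk2$gene, c("A", "M", "Z"))
  expect_equal(rk2$score, rep(0.5, 3))
})

test_that("hypergeometric enrichment matches exact tail probabilities", {
  # cluster of 5 genes identical to a 5-gene set in a background of 20:
  # p = P(X >= 5) = 1 / choose(20, 5)
  U <- rbind(matrix(rep(c(0.99, 0.01), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(0.01, 0.99), 15), 15, 2, byrow = TRUE))
  rownames(U) <- sprintf("G%02d", 1:20)
  fit <- new("FuzzyClustering", c = 2L, mFuzz = 2, membership = U,
             centroids = matrix(0, 2, 2), objective = 1, converged = TRUE,
             seed = 1L)
  gsc <- GeneSetCollection(list(TARGET = sprintf("G%02d", 1:5),
                                OTHER = sprintf("G%02d", 16:18)))
  enr <- enrichClusters(fit, gsc, sprintf("G%02d", 1:20))
  hit <- enr[enr$cluster == 1 & enr$set == "TARGET", ]
  expect_equal(hit$pValue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(hit$overlap, 5)
  # disjoint cluster x set: upper tail at overlap 0 is 1
  miss <- enr[enr$cluster == 1 & enr$set == "OTHER", ]
  expect_equal(miss$pValue, 1)
  expect_true(all(enr$fdr >= enr$pValue - 1e-12))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("selection returns genes of enriched clusters only", {
  U <- rbind(matrix(rep(c(0.95, 0.05), 10), 10, 2, byrow = TRUE),
             matrix(rep(c(0.05, 0.95), 10), 10, 2, byrow = TRUE))
  rownames(U) <- sprintf("G%02d", 1:20)
  fit <- new("FuzzyClustering", c = 2L, mFuzz = 2, membership = U,
             centroids = matrix(0, 2, 2), objective = 1, converged = TRUE,
             seed = 1L)
  gsc <- GeneSetCollection(list(TARGET = sprintf("G%02d", 1:8)))
  enr <- enrichClusters(fit, gsc, sprintf("G%02d", 1:20))
  sel <- selectPathwayGenes(fit, enr, "TARGET", fdrCutoff = 0.05)
  expect_setequal(sel, sprintf("G%02d", 1:10))
  expect_identical(selectPathwayGenes(fit, enr, "TARGET", fdrCutoff = 0),
                   character(0))
  expect_error(selectPathwayGenes(fit, enr, "NOPE"), "unknown")
})

test_that("planted co-expression block is detected at every cluster count", {
  co <- generateCohort(simulationConfig(
    nSamples = 150, nCases = 120, nControls = 30, nGenesExpression = 120,
    nGenesBurden = 10, nSignalGenes = 4, latentDimTrue = 4, nBlocks = 4,
    seed = 21))
  truth <- plantedTruthReport(co)
  block1 <- truth$gene[truth$omics == "expression" & truth$block == 1]
  allg <- truth$gene[truth$omics == "expression"]
  set.seed(33)
  gsc <- GeneSetCollection(list(
    ALS = c(block1, sample(setdiff(allg, block1), 5)),
    DECOY = sample(allg, 30)))
  # at every scanned cluster count, at least one cluster is associated
  # with the target pathway and yields a non-empty selection
  for (c in 6:12) {
    sel <- selectGenes(co@expression, gsc, "ALS", c = c, seed = c)
    expect_gt(length(sel$genes), 0)
    expect_gte(mean(block1 %in% sel$genes), 0.9)
  }
  # seeded single fit at the default granularity recovers the block
  sel8 <- selectGenes(co@expression, gsc, "ALS", c = 8, seed = 8)
  expect_gte(mean(block1 %in% sel8$genes), 0.95)
})
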