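# Evaluation harness: stratified folds, metric definitions against hand
# computations and independent implementations, and the IPCW Brier score
# against direct summation.

test_that("stratified folds preserve class proportions and determinism", {
  labels <- rep(c("maj", "min"), c(80, 20))
  f <- stratifiedKfold(labels, k = 5, seed = 3)
  for (k in 0:4) {
    expect_equal(sum(f == k & labels == "maj"), 16)
    expect_equal(sum(f == k & labels == "min"), 4)
  }
  expect_identical(f, stratifiedKfold(labels, k = 5, seed = 3))
  # cohort-scale imbalance: minority per fold in {15, 16}
  labels2 <- rep(c("case", "control"), c(593, 79))
  f2 <- stratifiedKfold(labels2, k = 5, seed = 1)
  minPerFold <- table(f2[labels2 == "control"])
  expect_true(all(minPerFold %in% c(15, 16)))
  expect_error(stratifiedKfold(rep(c("a", "b"), c(50, 3)), k = 5), "b")
})

test_that("classification metrics reproduce the hand confusion table", {
  perfect <- classificationMetrics(factor(c(1, 1, 0, 0)),
                                   factor(c(1, 1, 0, 0)),
                                   c(0.9, 0.8, 0.1, 0.2), positive = "1")
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1, auc = 1))
  half <- classificationMetrics(factor(c(1, 1, 0, 0)),
                                factor(c(1, 0, 1, 0)), positive = "1")
  expect_equal(half$accuracy, 0.5)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 0.5)
  # reversing the ranking flips the AUC
  set.seed(6)
  y <- factor(rep(c(0, 1), each = 10))
  p <- runif(20)
  a <- classificationMetrics(y, y, p, positive = "1")$auc
  b <- classificationMetrics(y, y, -p, positive = "1")$auc
  expect_equal(a, 1 - b)
  expect_error(classificationMetrics(factor(c(1, 1)), factor(c(1, 1)),
                                     c(0.5, 0.6)), "single class")
})

test_that("rank-statistic AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (rep in 1:5) {
    y <- rep(c(0, 1), c(15, 10))
    p <- rnorm(25) + y
    ours <- classificationMetrics(factor(y), factor(y), p,
                                  positive = "1")$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("regression metrics match hand arithmetic", {
  m <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(rmse = 0, mae = 0, medae = 0, r2 = 1))
  expect_warning(m2 <- regressionMetrics(c(0, 0, 0, 0), c(1, 1, 1, 3)),
                 "constant")
  expect_true(is.na(m2$r2))
  expect_equal(m2$mae, 1.5)
  expect_equal(m2$medae, 1)
  expect_equal(m2$rmse, sqrt(3))
  # predicting the mean gives exactly zero explained variance
  y <- c(2, 4, 9)
  m3 <- regressionMetrics(y, rep(mean(y), 3))
  expect_equal(m3$r2, 0)
  expect_warning(regressionMetrics(c(1, 1), c(0, 2)), "constant")
})

test_that("concordance index enumerates comparable pairs correctly", {
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 1, 0), c(2, 3, 1)), 2 / 3)
  expect_equal(concordanceIndex(1:5, rep(1, 5), 5:1), 1)
  r <- c(3, 1, 2)
  expect_equal(concordanceIndex(1:3, rep(1, 3), r) +
                 concordanceIndex(1:3, rep(1, 3), -r), 1)
  expect_error(concordanceIndex(c(1, 2), c(0, 1), c(1, 2)), "comparable")
  # random risks hover at 1/2
  set.seed(4)
  cs <- replicate(50, {
    t <- rexp(60); e <- rbinom(60, 1, 0.7); r <- rnorm(60)
    concordanceIndex(t, e, r)
  })
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("concordance matches survival::concordance on censored data", {
  set.seed(17)
  for (rep in 1:5) {
    t <- rexp(40); e <- rbinom(40, 1, 0.6); r <- rnorm(40)
    ours <- concordanceIndex(t, e, r)
    ref <- survival::concordance(survival::Surv(t, e) ~ r,
                                 reverse = TRUE)$concordance
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("integrated Brier score matches direct summation", {
  # constant half-probability curve without censoring: 0.25 everywhere
  g <- new("TimeGrid", boundaries = c(0, 1, 2, 3))
  S <- matrix(0.5, 5, 3)
  tt <- c(0.5, 1.5, 1.7, 2.5, 2.9)
  ee <- rep(1, 5)
  expect_equal(integratedBrierScore(S, g, tt, ee), 0.25, tolerance = 1e-12)
  # perfect step-function predictions give an IBS of 0
  g2 <- new("TimeGrid", boundaries = c(0, 1, 2))
  S2 <- rbind(c(0, 0), c(1, 0))  # events in intervals 1 and 2
  expect_equal(integratedBrierScore(S2, g2, c(0.5, 1.5), c(1, 1)), 0,
               tolerance = 1e-12)
  # hand-sized example: 3 subjects, 2 time points, no censoring
  g3 <- new("TimeGrid", boundaries = c(0, 2, 4))
  S3 <- rbind(c(0.9, 0.5), c(0.4, 0.2), c(0.8, 0.7))
  t3 <- c(3, 1, 5); e3 <- rep(1, 3)
  bsAt <- function(t, col) {
    mean(ifelse(t3 <= t, S3[, col]^2, (1 - S3[, col])^2))
  }
  direct <- (bsAt(2, 1) + bsAt(4, 2)) / 2  # trapezoid over two points
  expect_equal(integratedBrierScore(S3, g3, t3, e3), direct,
               tolerance = 1e-12)
})

test_that("Cohen's d uses the pooled standard deviation", {
  set.seed(5)
  x <- rnorm(50, 1, 1); y <- rnorm(50, 0, 1)
  d <- cohensD(x, y)
  sp <- sqrt((49 * var(x) + 49 * var(y)) / 98)
  expect_equal(d, (mean(x) - mean(y)) / sp)
})

test_that("cross-validation recovers planted signal on a small cohort", {
  co <- generateCohort(simulationConfig(
    nSamples = 180, nCases = 135, nControls = 45, nGenesExpression = 40,
    nGenesBurden = 12, nSignalGenes = 5, latentDimTrue = 2, nBlocks = 2,
    seed = 12))
  blocks <- list(expression = co@expression, burden = co@burden)
  cfg <- moalsTrainConfig(latentDim = 8, hidden = c(24), headHidden = c(8),
                          epochs1 = 20, epochs2 = 60, epochs3 = 30,
                          mIntervals = 6, seed = 4)
  cv <- suppressMessages(crossValidate(blocks, co@samples, cfg, k = 3,
                                       seed = 4))
  expect_equal(nrow(cv$perFold), 3)
  expect_gt(cv$pooled$auc, 0.8)
  expect_gt(cv$pooled$cIndex, 0.6)
  expect_true(all(is.finite(unlist(cv$ci))))
  # predicted probabilities separate the groups
  expect_gt(cv$cohensD, 0.5)
})
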