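# GradNorm machinery and the three-stage training protocol: joint loss,
# balancing loss, weight updates, gradient norms on a hand-solvable toy
# model, the stage-2 freeze, and seeded descent.

test_that("joint downstream loss is the weighted mean over tasks", {
  expect_equal(jointDownstreamLoss(0.7, 1), 0.7)
  expect_equal(jointDownstreamLoss(c(2, 4), c(1, 1)), 3)
  expect_equal(jointDownstreamLoss(c(2, 4), c(2, 2)), 6)
  expect_error(jointDownstreamLoss(c(1, 2), 1), "length")
})

test_that("gradnorm loss vanishes in the balanced case and hand-evaluates", {
  bal <- gradnormLoss(c(3, 3), c(1, 1), c(0.5, 0.5), alpha = 1.5)
  expect_equal(bal$loss, 0)
  expect_equal(bal$rates, c(1, 1))
  # G = (4, 2), equal rates, alpha = 1: targets are the mean norm 3
  gn <- gradnormLoss(c(4, 2), c(1, 1), c(0.2, 0.2), alpha = 1)
  expect_equal(gn$loss, abs(4 - 3) + abs(2 - 3))
  # alpha = 0 removes the rate adjustment entirely
  gn0 <- gradnormLoss(c(4, 2), c(1, 1), c(0.9, 0.1), alpha = 0)
  expect_equal(unname(gn0$targets), c(3, 3))
  expect_error(gradnormLoss(c(1, 1), c(0, 1), c(1, 1)), "positive")
})

test_that("weight updates renormalize to K and clip at the floor", {
  w <- c(a = 1, b = 1)
  expect_equal(updateTaskWeights(w, c(0, 0)), w)
  w2 <- updateTaskWeights(c(a = 1, b = 1), c(-2, 2), lrW = 0.1)
  expect_equal(sum(w2), 2)
  expect_gt(w2[["a"]], w2[["b"]])
  expect_message(w3 <- updateTaskWeights(c(a = 1, b = 1), c(0, 50),
                                         lrW = 0.1), "clipping")
  expect_equal(sum(w3), 2)
  expect_true(all(w3 > 0))
})

test_that("task gradient norms match the analytic value on a linear toy", {
  # no encoder hidden layers, identity-like heads: the mu layer gradient
  # of each quadratic/linear loss is computable by hand
  model <- moalsModel(list(x = 2), latentDim = 2, hidden = integer(0),
                      headHidden = integer(0),
                      tasks = c("classification", "regression"),
                      nClasses = 2, seed = 3)
  # freeze to known parameters: mu = X %*% Wmu, regression head = sum(mu)
  model@params$mu.W <- diag(2)
  model@params$mu.b <- c(0, 0)
  model@params$lv.W[] <- 0; model@params$lv.b <- c(0, 0)
  model@params$head.regressionOut.W <- matrix(c(1, 1), 2, 1)
  model@params$head.regressionOut.b <- 0
  model@params$head.classificationOut.W <- matrix(0, 2, 2)
  model@params$head.classificationOut.b <- c(0, 0)
  model@scalers <- list(x = structure(
    list(min = c(0, 0), max = c(1, 1), features = c("F1", "F2"),
         transform = "identity"), class = "moalsScaler"))
  model@classLevels <- c("n", "y")
  X <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2,
              dimnames = list(c("S1", "S2"), c("F1", "F2")))
  tab <- data.frame(sample = c("S1", "S2"), label = factor(c("n", "y")),
                    onset_age = c(1, 2), time = c(5, 6), event = c(1, 1))
  # regression target standardized with center 1.5, sd sqrt(0.5)
  model@onsetScale <- c(mean(tab$onset_age), sd(tab$onset_age))
  blocks <- list(x = OmicsBlock(X, "x"))
  G <- taskGradientNorms(model, blocks, tab)
  # hand derivation, regression: pred_i = mu_i1 + mu_i2 = x_i1 + x_i2,
  # L = mean((pred - y*)^2), dL/dmu = 2 (pred - y*) [1,1] / n,
  # dWmu = X^T dMu, db = colSums(dMu)
  ystar <- (tab$onset_age - model@onsetScale[1]) / model@onsetScale[2]
  pred <- rowSums(X)
  dMu <- matrix(2 * (pred - ystar) / 2, 2, 2)
  gW <- crossprod(X, dMu); gb <- colSums(dMu)
  expect_equal(unname(G[["regression"]]),
               sqrt(sum(gW^2) + sum(gb^2)), tolerance = 1e-6)
  # classification head has zero weights: loss is flat in mu -> G = 0
  expect_equal(unname(G[["classification"]]), 0)
  # scaling a task weight scales its gradient norm linearly
  model@taskWeights[["regression"]] <- 2
  G2 <- taskGradientNorms(model, blocks, tab)
  expect_equal(G2[["regression"]], 2 * G[["regression"]], tolerance = 1e-9)
})

test_that("stage 2 leaves every embedding parameter bitwise unchanged", {
  co <- smallCohort(seed = 4)
  blocks <- list(expression = co@expression, burden = co@burden)
  cfg <- tinyTrainConfig(epochs1 = 2, epochs2 = 0, epochs3 = 0, seed = 8)
  m1 <- trainMoals(blocks, co@samples, cfg)
  cfg2 <- tinyTrainConfig(epochs1 = 2, epochs2 = 3, epochs3 = 0, seed = 8)
  m2 <- trainMoals(blocks, co@samples, cfg2)
  for (nm in moals:::.paramNames(m1@spec, "embedding"))
    expect_identical(m1@params[[nm]], m2@params[[nm]])
  # heads did change
  headNames <- moals:::.paramNames(m1@spec, "heads")
  expect_true(any(vapply(headNames, function(nm)
    !identical(m1@params[[nm]], m2@params[[nm]]), logical(1))))
})

test_that("task weights stay near 1 for identical duplicated tasks", {
  # two tasks with the same loss structure and data keep balanced weights
  set.seed(20)
  K <- 2
  W <- c(a = 1, b = 1)
  for (it in 1:100) {
    g <- c(a = 2.0, b = 2.0)         # identical gradient norms
    G <- W * g
    gn <- gradnormLoss(G, c(1, 1), c(0.8, 0.8), alpha = 1.5)
    dW <- sign(G - gn$targets) * g
    W <- updateTaskWeights(W, dW, lrW = 0.01)
  }
  expect_lt(max(abs(W - 1)), 1e-3)
})

test_that("an under-trained task gains weight over GradNorm updates", {
  # task 1 trains slower (r1 > 1): its weight must increase monotonically
  W <- c(slow = 1, fast = 1)
  g <- c(slow = 1, fast = 1)
  trace <- numeric(10)
  for (it in 1:10) {
    G <- W * g
    gn <- gradnormLoss(G, c(1, 1), c(0.9, 0.3), alpha = 1)
    dW <- sign(G - gn$targets) * g
    W <- updateTaskWeights(W, dW, lrW = 0.02)
    trace[it] <- W[["slow"]]
  }
  expect_true(all(diff(c(1, trace)) > 0))
  expect_gt(W[["slow"]], W[["fast"]])
})

test_that("training descends and degenerate schedules are honoured", {
  co <- generateCohort(simulationConfig(
    nSamples = 200, nCases = 160, nControls = 40, nGenesExpression = 40,
    nGenesBurden = 12, nSignalGenes = 5, seed = 10))
  blocks <- list(expression = co@expression, burden = co@burden)
  cfg <- tinyTrainConfig(epochs1 = 4, epochs2 = 6, epochs3 = 6, seed = 2)
  fit <- trainMoals(blocks, co@samples, cfg)
  expect_true(fit@trained)
  # stage-3 training loss decreased from its first epoch
  expect_lt(tail(fit@history$stage3, 1), fit@history$stage3[1])
  # task weights sum to K after training
  expect_equal(sum(fit@taskWeights), length(fit@spec$heads))
  expect_true(all(fit@taskWeights > 0))
  # zero-epoch schedule returns the initialized model unchanged
  cfg0 <- tinyTrainConfig(epochs1 = 0, epochs2 = 0, epochs3 = 0, seed = 2)
  m0 <- trainMoals(blocks, co@samples, cfg0)
  init <- moalsModel(lapply(blocks, function(b) length(featureIDs(b))),
                     latentDim = cfg0$latentDim, hidden = cfg0$hidden,
                     headHidden = cfg0$headHidden,
                     mIntervals = cfg0$mIntervals, seed = cfg0$seed)
  expect_identical(m0@params, init@params)
})
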