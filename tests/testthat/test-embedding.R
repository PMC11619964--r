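# Deep embedding module: scaler contracts, encoder determinism and
# positivity link, reparameterization, closed-form KL against Monte
# Carlo, the per-block embedding loss, autodiff vs finite differences,
# and stage-1 descent.

test_that("min-max scaler maps training data into [0,1] with clipping", {
  m <- matrix(c(0, 10, 5, 5, 2, 8), 2, 3,
              dimnames = list(c("S1", "S2"), c("F1", "F2", "F3")))
  b <- OmicsBlock(m)
  sc <- fitMinmaxScaler(b, c("S1", "S2"))
  out <- applyScaler(sc, m)
  expect_equal(out[, "F1"], c(S1 = 0, S2 = 1))
  expect_equal(out[, "F2"], c(S1 = 0.5, S2 = 0.5))  # constant feature
  # unseen values clip into [0,1]
  test <- matrix(c(20, -5, 5, 5, 9, 1), 2, 3,
                 dimnames = list(c("T1", "T2"), c("F1", "F2", "F3")))
  outT <- applyScaler(sc, test)
  expect_equal(unname(outT[, "F1"]), c(1, 0))
  expect_true(all(outT >= 0 & outT <= 1))
})

test_that("encoder is deterministic with a strictly positive sigma link", {
  model <- moalsModel(list(expression = 6, burden = 2), latentDim = 3,
                      hidden = c(5), seed = 2)
  x <- matrix(runif(16), 2, 8)
  p1 <- encode(model, x)
  p2 <- encode(model, x)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$sigma, p2$sigma)
  set.seed(1)
  xs <- matrix(runif(1000 * 8), 1000, 8)
  expect_true(all(encode(model, xs)$sigma > 0))
  expect_error(encode(model, x[, 1:5]), "width")
})

test_that("zero-weight encoder returns its bias as the posterior mean", {
  model <- moalsModel(list(b = 4), latentDim = 3, hidden = integer(0),
                      seed = 1)
  model@params$mu.W[] <- 0
  model@params$mu.b <- c(0.3, -1, 2)
  post <- encode(model, matrix(runif(8), 2, 4))
  expect_equal(unname(post$mu), matrix(c(0.3, -1, 2), 2, 3, byrow = TRUE))
})

test_that("reparameterization is mu + sigma * eps with correct moments", {
  expect_equal(reparameterize(c(1, 2), c(2, 3), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(1, 2, 0.5), 2)
  set.seed(10)
  draws <- reparameterize(rep(1.5, 1e5), rep(0.7, 1e5))
  expect_lt(abs(mean(draws) - 1.5), 3 * 0.7 / sqrt(1e5))
  expect_lt(abs(sd(draws) - 0.7), 0.02)
})

test_that("closed-form KL matches Monte-Carlo estimates and is >= 0", {
  expect_equal(klClosedForm(rep(0, 5), rep(1, 5)), 0)
  expect_equal(klClosedForm(1, 1), 0.5)
  expect_error(klClosedForm(0, -1), "positive")
  set.seed(3)
  for (rep in 1:5) {
    mu <- rnorm(4, 0, 1)
    sigma <- exp(rnorm(4, 0, 0.3))
    kl <- klClosedForm(mu, sigma)
    expect_gte(kl, 0)
    z <- matrix(rnorm(1e6 * 4), ncol = 4)
    z <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
    logq <- -0.5 * rowSums(sweep((sweep(z, 2, mu))^2, 2, sigma^2, "/")) -
      sum(log(sigma))
    logp <- -0.5 * rowSums(z^2)
    expect_lt(abs(mean(logq - logp) - kl), 1e-2)
  }
  # KL = 0 only at the standard normal (grid check)
  for (mu in c(-1, 0.5)) expect_gt(klClosedForm(mu, 1), 0)
  for (s in c(0.5, 2)) expect_gt(klClosedForm(0, s), 0)
})

test_that("embedding loss averages BCE per block and adds the KL", {
  set.seed(4)
  x <- matrix(rbinom(20, 1, 0.5), 4, 5)
  xr <- pmin(pmax(x, 1e-7), 1 - 1e-7)
  loss <- embeddingLoss(list(x), list(xr), rep(0, 3), rep(1, 3))
  expect_lt(abs(loss), 1e-5)
  # maximal-entropy floor: x = xhat = 0.5 everywhere gives ln 2 per element
  h <- matrix(0.5, 3, 4)
  expect_equal(embeddingLoss(list(h), list(h), rep(0, 2), rep(1, 2)),
               log(2), tolerance = 1e-9)
  # two blocks: reconstruction term is the mean of per-block BCEs
  xa <- matrix(runif(12), 3, 4); xb <- matrix(runif(6), 3, 2)
  ra <- matrix(runif(12, 0.1, 0.9), 3, 4)
  rb <- matrix(runif(6, 0.1, 0.9), 3, 2)
  b1 <- embeddingLoss(list(xa), list(ra), rep(0, 2), rep(1, 2))
  b2 <- embeddingLoss(list(xb), list(rb), rep(0, 2), rep(1, 2))
  both <- embeddingLoss(list(xa, xb), list(ra, rb), rep(0, 2), rep(1, 2))
  expect_equal(both, (b1 + b2) / 2, tolerance = 1e-12)
  expect_error(embeddingLoss(list(xa), list(xa * 2), rep(0, 2), rep(1, 2)),
               "0, 1")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(42)
  n <- 6
  model <- moalsModel(list(e = 5, b = 3), latentDim = 3, hidden = c(6),
                      headHidden = c(4), mIntervals = 4, seed = 5)
  X <- matrix(runif(n * 8), n, 8)
  eps <- matrix(rnorm(n * 3), n, 3)
  params <- model@params
  spec <- model@spec
  lossAt <- function(p) {
    fw <- moals:::.modelForwardTrain(p, spec, X, eps = eps)
    moals:::.embedLossGrads(p, spec, fw, X, "mean")$loss
  }
  fw <- moals:::.modelForwardTrain(params, spec, X, eps = eps)
  eg <- moals:::.embedLossGrads(params, spec, fw, X, "mean")
  set.seed(7)
  for (k in sample(names(eg$grads), 6)) {
    i <- sample(length(params[[k]]), 1)
    h <- 1e-6
    p2 <- params; p2[[k]][i] <- p2[[k]][i] + h; up <- lossAt(p2)
    p2[[k]][i] <- p2[[k]][i] - 2 * h; dn <- lossAt(p2)
    num <- (up - dn) / (2 * h)
    expect_lt(abs(num - eg$grads[[k]][i]) /
                max(1e-6, abs(num) + abs(eg$grads[[k]][i])), 1e-4)
  }
})

test_that("one unsupervised epoch decreases the mean embedding loss", {
  co <- generateCohort(simulationConfig(
    nSamples = 200, nCases = 160, nControls = 40, nGenesExpression = 30,
    nGenesBurden = 10, nSignalGenes = 4, seed = 6))
  blocks <- list(expression = co@expression, burden = co@burden)
  cfg0 <- tinyTrainConfig(epochs1 = 0, epochs2 = 0, epochs3 = 0, seed = 3)
  cfg1 <- tinyTrainConfig(epochs1 = 1, epochs2 = 0, epochs3 = 0, seed = 3)
  m0 <- trainMoals(blocks, co@samples, cfg0)
  m1 <- trainMoals(blocks, co@samples, cfg1)
  evalLoss <- function(m) {
    prep <- moals:::.prepareBatchData(m, blocks, co@samples)
    fw <- moals:::.modelForwardTrain(m@params, m@spec, prep$X,
                                     sampleZ = FALSE)
    moals:::.embedLossGrads(m@params, m@spec, fw, prep$X)$loss
  }
  expect_lt(evalLoss(m1), evalLoss(m0))
})
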