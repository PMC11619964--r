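# Downstream heads: classification/regression losses, the survival time
# grid, monotone label encoding, the MTLR likelihood against brute-force
# enumeration, survival curves, and risk scores.

test_that("classification loss is the softmax cross-entropy", {
  expect_lt(classificationLoss(1L, c(30, 0)), 1e-10)
  expect_equal(classificationLoss(1L, c(0, 0)), log(2), tolerance = 1e-12)
  expect_equal(classificationLoss(1L, c(1, 0)), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_error(classificationLoss(3L, c(1, 0)), "class")
  # batch mean and class weighting
  logits <- rbind(c(2, 0), c(0, 2))
  expect_equal(classificationLoss(c(1L, 1L), logits),
               mean(c(-log(exp(2) / (exp(2) + 1)),
                      -log(1 / (1 + exp(2))))), tolerance = 1e-12)
})

test_that("regression loss is the mean squared error", {
  expect_equal(regressionLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(regressionLoss(c(0, 0), c(1, 3)), 5)
  e1 <- regressionLoss(c(0, 0), c(1, 2))
  expect_equal(regressionLoss(c(0, 0), c(2, 4)), 4 * e1)
})

test_that("time grid strategies produce strictly increasing boundaries", {
  g <- makeTimeGrid(1:100, 4, strategy = "uniform")
  b <- boundaries(g)
  expect_equal(b[1:4], c(0, 25, 50, 75))
  expect_gte(b[5], 100)
  expect_equal(nIntervals(makeTimeGrid(c(3, 9), 1)), 1)
  # quantile grid puts comparable event mass in each interval
  set.seed(2)
  tt <- rexp(500, 1 / 80)
  gq <- makeTimeGrid(tt, 5)
  counts <- table(cut(tt, boundaries(gq)))
  expect_true(all(counts >= 80))
  # heavy ties collapse boundaries with a warning, m shrinks
  expect_warning(gt <- makeTimeGrid(rep(c(5, 5, 5, 9), 25), 8), "reduced")
  expect_lt(nIntervals(gt), 8)
  expect_true(all(diff(boundaries(gt)) > 0))
  expect_error(makeTimeGrid(1:5, 0), "mIntervals")
})

test_that("survival labels encode the event interval monotonically", {
  g <- new("TimeGrid", boundaries = c(0, 10, 20, 30))
  expect_equal(encodeSurvivalLabel(15, 1, g)$y, c(0L, 1L, 1L))
  expect_equal(encodeSurvivalLabel(5, 1, g)$y, c(1L, 1L, 1L))
  lab <- encodeSurvivalLabel(15, 0, g)
  expect_equal(lab$interval, 2L)
  expect_true(all(is.na(lab$y)))
  expect_warning(late <- encodeSurvivalLabel(99, 1, g), "last interval")
  expect_equal(late$interval, 3L)
})

test_that("MTLR probabilities normalize over monotone configurations", {
  # uniform configurations under zero scores
  expect_equal(exp(mtlrLogProbability(c(1, 1), c(0, 0))), 1 / 3)
  # hand example: m = 2, y' = (ln 2, 0), y = (1,1): 2 / (2 + 1 + 1)
  expect_equal(exp(mtlrLogProbability(c(1, 1), c(log(2), 0))), 0.5)
  expect_error(mtlrLogProbability(c(1, 0), c(0, 0)), "monotone")
  # brute-force enumeration: sum over all m + 1 configurations is 1,
  # and each matches the naive direct formula
  set.seed(9)
  for (m in 1:6) {
    ys <- rnorm(m, 0, 2)
    probs <- vapply(enumerateMonotoneLabels(m), function(y)
      exp(mtlrLogProbability(y, ys)), numeric(1))
    expect_lt(abs(sum(probs) - 1), 1e-9)
    naive <- vapply(enumerateMonotoneLabels(m), bruteForceMtlrProb,
                    numeric(1), ys = ys)
    expectNoDiff(probs, naive, 1e-9)
  }
  # log-sum-exp guard: huge scores do not overflow
  expect_true(is.finite(mtlrLogProbability(c(0, 1), c(800, -800))))
})

test_that("survival loss handles censoring by marginalization", {
  g <- new("TimeGrid", boundaries = c(0, 10, 20))
  ev <- encodeSurvivalLabel(5, 1, g)
  # uncensored: exactly the negative log-probability
  set.seed(5)
  ys <- rnorm(2)
  expect_equal(survivalLoss(list(ev), rbind(ys)),
               -mtlrLogProbability(ev$y, ys))
  # zero scores: -log(1/3) for any event
  expect_equal(survivalLoss(list(ev), rbind(c(0, 0))), log(3))
  # censored in the last interval: 2 of 3 configurations compatible
  cs <- encodeSurvivalLabel(15, 0, g)
  expect_equal(survivalLoss(list(cs), rbind(c(0, 0))), -log(2 / 3))
  # batch mean
  expect_equal(survivalLoss(list(ev, cs), rbind(c(0, 0), c(0, 0))),
               mean(c(log(3), -log(2 / 3))))
  expect_error(survivalLoss(list(), matrix(0, 0, 2)), "empty")
})

test_that("survival curves are proper and risk follows discrete hazards", {
  g <- new("TimeGrid", boundaries = c(0, 10, 20))
  S <- predictSurvivalCurve(c(0, 0), g)
  expect_equal(unname(S), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(riskScore(c(0, 0), g), 1 / 3 + 1 / 2, tolerance = 1e-12)
  # event certain in interval 1 under huge positive scores
  Shuge <- predictSurvivalCurve(c(50, 50), g)
  expect_lt(Shuge[1], 1e-10)
  # monotone and within [0,1] for 1000 random score vectors
  set.seed(12)
  g5 <- new("TimeGrid", boundaries = c(0, 1, 2, 3, 4, 5))
  ok <- TRUE
  for (i in 1:1000) {
    ys <- rnorm(5, 0, 3)
    S <- predictSurvivalCurve(ys, g5)
    ok <- ok && all(diff(S) <= 1e-12) && all(S >= -1e-12 & S <= 1 + 1e-12)
  }
  expect_true(ok)
})

test_that("probabilities are invariant to shifting the configuration scores", {
  # the softmax over configurations is shift-invariant in the suffix
  # scores s_j (not in y' itself, whose shift enters each configuration
  # with a different multiplicity)
  set.seed(13)
  ys <- rnorm(4, 0, 2)
  s <- moals:::.suffixScores(ys)
  for (shift in c(-3, 2, 10)) {
    p0 <- exp(s - moals:::.logSumExp(s))
    p1 <- exp((s + shift) - moals:::.logSumExp(s + shift))
    expectNoDiff(p0, p1, 1e-12)
  }
})
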