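# Stratified cross-validation harness and the reported metrics:
# classification (accuracy/precision/recall/F1, rank-statistic AUC),
# regression (RMSE/MAE/MedAE/R^2), survival (Harrell's C-index and the
# IPCW integrated Brier score).

#' Stratified k-fold assignment
#'
#' Deterministic, seeded partition of samples into k folds preserving the
#' class proportions: within every class, shuffled members are dealt
#' round-robin to folds, so per-fold class counts differ by at most one.
#'
#' @param labels factor (or coercible) of class labels.
#' @param k number of folds (default 5); every class must have >= k
#'   members.
#' @param seed integer seed.
#' @return integer vector of fold indices in 0..k-1, one per sample.
#' @export
stratifiedKfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  k <- as.integer(k)
  small <- names(which(table(labels) < k))
  if (length(small))
    stop(sprintf("class '%s' has fewer than k = %d members", small[1], k))
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- (seq_along(idx) - 1L) %% k
  }
  fold
}

#' Classification metrics
#'
#' Standard binary/multiclass metrics with the declared positive class:
#' accuracy, precision, recall, F1 (all on the positive class), and — for
#' binary problems with probabilities supplied — AUC computed via the
#' rank statistic (equivalent to the Mann-Whitney U), with ties sharing
#' mid-ranks.
#'
#' @param yTrue,yPred factors (or coercible) of true and predicted
#'   labels.
#' @param yProb optional numeric vector of predicted positive-class
#'   probabilities or scores.
#' @param positive the positive class label (default: last factor level).
#' @return named list: accuracy, precision, recall, f1, auc (NA if no
#'   probabilities; error if yTrue has a single class).
#' @export
classificationMetrics <- function(yTrue, yPred, yProb = NULL,
                                  positive = NULL) {
  yTrue <- as.factor(yTrue)
  if (is.null(positive)) positive <- levels(yTrue)[nlevels(yTrue)]
  yPred <- factor(as.character(yPred), levels = levels(yTrue))
  pos <- yTrue == positive
  posHat <- yPred == positive
  tp <- sum(pos & posHat); fp <- sum(!pos & posHat)
  fn <- sum(pos & !posHat)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  auc <- NA_real_
  if (!is.null(yProb)) {
    if (length(unique(yTrue)) < 2)
      stop("AUC undefined: yTrue contains a single class")
    r <- rank(yProb)
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(accuracy = mean(yTrue == yPred), precision = precision,
       recall = recall, f1 = f1, auc = auc)
}

#' Regression metrics
#'
#' RMSE, MAE, MedAE and \eqn{R^2 = 1 - SSE/SST}.
#'
#' @param yTrue,yPred aligned finite numeric vectors; a constant yTrue
#'   makes R^2 undefined (returned as `NA` with a warning; the error
#'   metrics are still reported).
#' @return named list: rmse, mae, medae, r2.
#' @export
regressionMetrics <- function(yTrue, yPred) {
  ok <- is.finite(yTrue) & is.finite(yPred)
  yTrue <- yTrue[ok]; yPred <- yPred[ok]
  if (!length(yTrue)) stop("no finite pairs")
  err <- yTrue - yPred
  sst <- sum((yTrue - mean(yTrue))^2)
  r2 <- if (sst == 0) {
    warning("R^2 undefined: constant yTrue")
    NA_real_
  } else 1 - sum(err^2) / sst
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       medae = median(abs(err)), r2 = r2)
}

#' Harrell's concordance index
#'
#' Over all pairs comparable under censoring (the member with the earlier
#' observed time experienced the event), the fraction in which that
#' earlier-event member carries the higher predicted risk; risk ties
#' count 0.5. Pairs with equal times and both events are incomparable
#' under this (strict Harrell) definition.
#'
#' @param time observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param risk predicted risk scores (higher = earlier expected event).
#' @return C-index in [0, 1]; error when no comparable pair exists.
#' @export
concordanceIndex <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comparable <- time > time[i]
    if (any(comparable)) {
      den <- den + sum(comparable)
      num <- num + sum(risk[i] > risk[comparable]) +
        0.5 * sum(risk[i] == risk[comparable])
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Integrated Brier score with IPCW weighting
#'
#' The Brier score at grid time t weights each subject by the inverse
#' probability of remaining uncensored (Kaplan-Meier estimate of the
#' censoring distribution G): subjects with an observed event by t
#' contribute \eqn{S_i(t)^2 / G(T_i^-)}, subjects still at risk
#' contribute \eqn{(1 - S_i(t))^2 / G(t)}. Scores are integrated over the
#' grid by the trapezoid rule and normalized by the spanned time. If G
#' reaches 0 before the last needed time, integration is truncated with a
#' warning.
#'
#' @param sCurves samples x m matrix of predicted survival probabilities
#'   at the grid's upper boundaries.
#' @param grid the [TimeGrid-class] the curves live on.
#' @param time,event observed times and event indicators.
#' @return scalar IBS in [0, 1].
#' @export
integratedBrierScore <- function(sCurves, grid, time, event) {
  if (!is.matrix(sCurves)) sCurves <- matrix(sCurves, nrow = 1)
  m <- nIntervals(grid)
  stopifnot(ncol(sCurves) == m, nrow(sCurves) == length(time))
  ts <- boundaries(grid)[-1]
  # censoring KM: G(t) = P(censoring time > t)
  cens <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    # left-continuous evaluation G(t^-) handled via small epsilon by caller;
    # summary() needs sorted times, so sort and map back
    o <- order(t)
    s <- summary(cens, times = t[o], extend = TRUE)$surv
    s[order(o)]
  }
  Gt <- G(ts)
  GTiMinus <- G(pmax(time - 1e-12 * pmax(time, 1), 0))
  bs <- rep(NA_real_, m)
  usable <- rep(TRUE, m)
  n <- length(time)
  for (j in seq_len(m)) {
    t <- ts[j]
    hadEvent <- time <= t & event == 1
    atRisk <- time > t
    wEvent <- ifelse(hadEvent & GTiMinus > 0, 1 / GTiMinus, 0)
    wRisk <- if (Gt[j] > 0) 1 / Gt[j] else 0
    if ((any(hadEvent & GTiMinus == 0)) || (any(atRisk) && Gt[j] == 0)) {
      usable[j] <- FALSE
      next
    }
    bs[j] <- sum(sCurves[, j]^2 * hadEvent * wEvent +
                 (1 - sCurves[, j])^2 * atRisk * wRisk) / n
  }
  lastUsable <- if (all(usable)) m else {
    warning("censoring distribution reaches 0; integration truncated")
    max(which(cumsum(!usable) == 0), 0)
  }
  if (lastUsable < 1) stop("no usable grid times for the Brier score")
  tt <- ts[seq_len(lastUsable)]
  bb <- bs[seq_len(lastUsable)]
  if (lastUsable == 1) return(bb)
  sum(diff(tt) * (head(bb, -1) + bb[-1]) / 2) / (tt[lastUsable] - tt[1])
}

#' Cohen's d between two groups
#'
#' Mean difference divided by the pooled standard deviation.
#'
#' @param x,y numeric vectors for the two groups.
#' @return scalar effect size.
#' @export
cohensD <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

.tCI <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  se <- sd(x) / sqrt(n)
  mean(x) + c(-1, 1) * qt(1 - (1 - level) / 2, n - 1) * se
}

#' Stratified cross-validation of the full multi-task model
#'
#' Runs k-fold cross-validation: per fold, scalers, the onset
#' normalization and the survival grid are fitted on the training split
#' only (inside [trainMoals()]), the model is trained, and the held-out
#' fold is predicted. Reports per-fold and pooled metrics with 95%
#' t-based confidence intervals across folds, plus Cohen's d between the
#' predicted positive-class probabilities of the two classes.
#'
#' @param blocks named list of [OmicsBlock-class] objects.
#' @param sampleTable aligned sample metadata.
#' @param config a [moalsTrainConfig()].
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment; fold f's model is trained
#'   with \code{config$seed + f}.
#' @param positive positive class label (default: last level).
#' @return list with \code{perFold} (data.frame of fold metrics),
#'   \code{pooled} (metrics on concatenated held-out predictions),
#'   \code{ci} (95% CIs across folds), \code{cohensD}, \code{folds},
#'   and \code{predictions} (pooled held-out predictions).
#' @export
crossValidate <- function(blocks, sampleTable, config = moalsTrainConfig(),
                          k = 5L, seed = 1L, positive = NULL) {
  al <- alignSamples(blocks, sampleTable)
  blocks <- al$blocks
  sampleTable <- al$sampleTable
  if (is.null(positive))
    positive <- levels(sampleTable$label)[nlevels(sampleTable$label)]
  folds <- stratifiedKfold(sampleTable$label, k = k, seed = seed)
  n <- nrow(sampleTable)
  pooled <- data.frame(sample = sampleTable$sample,
                       label = sampleTable$label,
                       onset_age = sampleTable$onset_age,
                       time = sampleTable$time, event = sampleTable$event,
                       fold = folds, prob = NA_real_,
                       pred = factor(rep(levels(sampleTable$label)[1], n),
                                     levels = levels(sampleTable$label)),
                       onsetPred = NA_real_, risk = NA_real_,
                       stringsAsFactors = FALSE)
  perFold <- list()
  for (f in sort(unique(folds))) {
    te <- folds == f
    trIdx <- which(!te); teIdx <- which(te)
    subBlocks <- lapply(blocks, function(b)
      OmicsBlock(blockValues(b)[trIdx, , drop = FALSE], blockName(b)))
    teBlocks <- lapply(blocks, function(b)
      OmicsBlock(blockValues(b)[teIdx, , drop = FALSE], blockName(b)))
    cfgF <- config
    cfgF$seed <- config$seed + f
    fit <- trainMoals(subBlocks, sampleTable[trIdx, , drop = FALSE], cfgF)
    pr <- predictMoals(fit, teBlocks)
    row <- list(fold = f)
    if (!is.null(pr$classProb)) {
      prob <- pr$classProb[, positive]
      pooled$prob[teIdx] <- prob
      pooled$pred[teIdx] <- pr$classPred
      cm <- classificationMetrics(sampleTable$label[teIdx], pr$classPred,
                                  prob, positive = positive)
      row <- c(row, cm)
    }
    if (!is.null(pr$onset)) {
      pooled$onsetPred[teIdx] <- pr$onset
      rm_ <- regressionMetrics(sampleTable$onset_age[teIdx], pr$onset)
      row <- c(row, rm_)
    }
    if (!is.null(pr$risk)) {
      pooled$risk[teIdx] <- pr$risk
      row$cIndex <- concordanceIndex(sampleTable$time[teIdx],
                                     sampleTable$event[teIdx], pr$risk)
      row$ibs <- integratedBrierScore(pr$survivalCurves, fit@timeGrid,
                                      sampleTable$time[teIdx],
                                      sampleTable$event[teIdx])
    }
    perFold[[length(perFold) + 1L]] <- as.data.frame(row)
  }
  perFold <- do.call(rbind, perFold)

  pooledMetrics <- list()
  if (!all(is.na(pooled$prob))) {
    pooledMetrics <- c(pooledMetrics,
      classificationMetrics(pooled$label, pooled$pred, pooled$prob,
                            positive = positive))
  }
  if (!all(is.na(pooled$onsetPred)))
    pooledMetrics <- c(pooledMetrics,
      regressionMetrics(pooled$onset_age, pooled$onsetPred))
  if (!all(is.na(pooled$risk))) {
    pooledMetrics$cIndex <- concordanceIndex(pooled$time, pooled$event,
                                             pooled$risk)
  }
  ci <- lapply(perFold[setdiff(colnames(perFold), "fold")], .tCI)
  d <- if (!all(is.na(pooled$prob)))
    cohensD(pooled$prob[pooled$label == positive],
            pooled$prob[pooled$label != positive]) else NA_real_
  list(perFold = perFold, pooled = pooledMetrics, ci = ci, cohensD = d,
       folds = folds, predictions = pooled)
}
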