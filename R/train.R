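# Three-stage training protocol:
#   stage 1 (unsupervised): embedding loss only, encoder + decoder updated.
#   stage 2: embedding frozen, heads trained on the weighted joint
#            downstream loss.
#   stage 3: joint fine-tune of everything on L_embed + L_down, with
#            GradNorm updating the task weights every iteration.

#' Training configuration
#'
#' Defaults follow the reference hyperparameters (latent dimension 128,
#' batch size 32, 50 unsupervised + 100 supervised epochs, learning rate
#' 1e-3); every field is overridable. \code{epochs3} (joint fine-tuning
#' length) and the GradNorm strength \code{alpha} are additional knobs of
#' this implementation.
#'
#' @param latentDim,hidden,headHidden architecture (see [moalsModel()]).
#' @param tasks downstream tasks to attach.
#' @param mIntervals,gridStrategy survival time grid (see
#'   [makeTimeGrid()]).
#' @param epochs1,epochs2,epochs3 per-stage epoch counts (>= 0).
#' @param lr Adam learning rate.
#' @param lrW GradNorm task-weight learning rate.
#' @param batchSize minibatch size (>= 1).
#' @param alpha GradNorm balancing strength.
#' @param gradnorm run GradNorm weight updates in stage 3 (default TRUE;
#'   FALSE keeps W_k = 1).
#' @param classWeights use inverse-frequency class weights in the
#'   classification loss (default FALSE).
#' @param logTransformBlocks names of blocks to log1p-transform before
#'   min-max scaling (default \code{"expression"}: abundance data is
#'   scaled on the log scale; count-like burden blocks are left as is).
#' @param reconReduction reconstruction reduction in the training
#'   objective: \code{"sum"} (default) treats the per-block BCE as the
#'   Bernoulli log-likelihood summed over the block's features — the ELBO
#'   reconstruction term, which keeps reconstruction and KL on comparable
#'   scales and prevents posterior collapse; \code{"mean"} averages over
#'   elements within each block.
#' @param seed integer seed controlling initialization, shuffling and
#'   reparameterization noise.
#' @return list of class \code{moalsTrainConfig}.
#' @export
moalsTrainConfig <- function(latentDim = 128L, hidden = c(512L, 256L),
                             headHidden = c(64L),
                             tasks = c("classification", "regression",
                                       "survival"),
                             mIntervals = 10L,
                             gridStrategy = c("quantile", "uniform"),
                             epochs1 = 50L, epochs2 = 100L, epochs3 = 20L,
                             lr = 1e-3, lrW = 0.025, batchSize = 32L,
                             alpha = 1.5, gradnorm = TRUE,
                             classWeights = FALSE,
                             logTransformBlocks = "expression",
                             reconReduction = c("sum", "mean"),
                             seed = 1L) {
  gridStrategy <- match.arg(gridStrategy)
  stopifnot(epochs1 >= 0, epochs2 >= 0, epochs3 >= 0, batchSize >= 1)
  structure(list(latentDim = as.integer(latentDim),
                 hidden = as.integer(hidden),
                 headHidden = as.integer(headHidden), tasks = tasks,
                 mIntervals = as.integer(mIntervals),
                 gridStrategy = gridStrategy,
                 epochs1 = as.integer(epochs1),
                 epochs2 = as.integer(epochs2),
                 epochs3 = as.integer(epochs3), lr = lr, lrW = lrW,
                 batchSize = as.integer(batchSize), alpha = alpha,
                 gradnorm = isTRUE(gradnorm),
                 classWeights = isTRUE(classWeights),
                 logTransformBlocks = logTransformBlocks,
                 reconReduction = match.arg(reconReduction),
                 seed = as.integer(seed)),
            class = "moalsTrainConfig")
}

.checkFinite <- function(loss, stage, epoch) {
  if (!is.finite(loss))
    stop(sprintf("non-finite loss in stage %d, epoch %d — aborting",
                 stage, epoch))
}

#' Train a MOALS model on aligned omics blocks
#'
#' Fits min-max scalers and the survival time grid on the supplied
#' (training) samples, initializes a [moalsModel()], and runs the
#' three-stage protocol. Stage 2 provably leaves every embedding
#' parameter untouched; GradNorm task weights are renormalized to sum to
#' the task count after every update. All randomness derives from
#' \code{config$seed}.
#'
#' @param blocks named list of [OmicsBlock-class] objects (e.g.
#'   expression + burden), sample-aligned with \code{sampleTable}.
#' @param sampleTable sample metadata (see [readSampleTable()]).
#' @param config a [moalsTrainConfig()].
#' @return a trained [MoalsModel-class] with per-stage loss history.
#' @export
trainMoals <- function(blocks, sampleTable, config = moalsTrainConfig()) {
  stopifnot(inherits(config, "moalsTrainConfig"))
  al <- alignSamples(blocks, sampleTable)
  blocks <- al$blocks
  sampleTable <- al$sampleTable
  n <- nrow(sampleTable)

  blockDims <- lapply(blocks, function(b) length(featureIDs(b)))
  model <- moalsModel(blockDims, latentDim = config$latentDim,
                      hidden = config$hidden, tasks = config$tasks,
                      headHidden = config$headHidden,
                      nClasses = max(2L, nlevels(sampleTable$label)),
                      mIntervals = config$mIntervals, seed = config$seed)
  model@scalers <- lapply(names(blocks), function(nm)
    fitMinmaxScaler(blocks[[nm]],
                    transform = if (nm %in% config$logTransformBlocks)
                      "log1p" else "identity"))
  names(model@scalers) <- names(blocks)
  model@classLevels <- levels(sampleTable$label)

  if ("regression" %in% config$tasks) {
    ons <- sampleTable$onset_age[!is.na(sampleTable$onset_age)]
    ctr <- if (length(ons)) mean(ons) else 0
    scl <- if (length(ons) > 1 && sd(ons) > 0) sd(ons) else 1
    model@onsetScale <- c(ctr, scl)
  }
  if ("survival" %in% config$tasks) {
    ok <- !is.na(sampleTable$time) & !is.na(sampleTable$event)
    evTimes <- sampleTable$time[ok & sampleTable$event == 1]
    if (!length(evTimes)) evTimes <- sampleTable$time[ok]
    if (length(evTimes)) {
      grid <- makeTimeGrid(evTimes, config$mIntervals, config$gridStrategy)
      # ensure censored times also fall inside the grid
      tAll <- max(sampleTable$time[ok])
      b <- boundaries(grid)
      if (tAll >= b[length(b)]) b[length(b)] <- tAll * (1 + 1e-9)
      model@timeGrid <- new("TimeGrid", boundaries = b)
      m <- nIntervals(model@timeGrid)
      if (m != config$mIntervals) {
        # tied quantiles reduced the grid; rebuild the survival head
        model <- .resizeSurvivalHead(model, m)
      }
    }
  }

  classWeights <- NULL
  if (config$classWeights && "classification" %in% config$tasks) {
    freq <- table(factor(sampleTable$label, levels = model@classLevels))
    classWeights <- as.numeric(sum(freq) / (length(freq) * pmax(freq, 1)))
  }

  prep <- .prepareBatchData(model, blocks, sampleTable, classWeights)
  X <- prep$X
  targets <- prep$targets
  spec <- model@spec
  params <- model@params
  embedNames <- .paramNames(spec, "embedding")
  headNames <- .paramNames(spec, "heads")
  K <- length(spec$heads)
  W <- model@taskWeights

  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(config$seed + 1L)
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))

  history <- list(stage1 = numeric(0), stage2 = numeric(0),
                  stage3 = numeric(0),
                  taskWeights = matrix(NA_real_, 0, K,
                                       dimnames = list(NULL, names(W))))
  batches <- function() {
    idx <- sample.int(n)
    split(idx, ceiling(seq_along(idx) / config$batchSize))
  }

  # ---- stage 1: unsupervised embedding training
  opt <- .adamInit(params)
  for (ep in seq_len(config$epochs1)) {
    tot <- 0
    for (bt in batches()) {
      fw <- .modelForwardTrain(params, spec, X[bt, , drop = FALSE])
      eg <- .embedLossGrads(params, spec, fw, X[bt, , drop = FALSE],
                            config$reconReduction)
      st <- .adamStep(params, eg$grads, opt, config$lr, only = embedNames)
      params <- st$params; opt <- st$state
      tot <- tot + eg$loss * length(bt)
    }
    .checkFinite(tot / n, 1L, ep)
    history$stage1 <- c(history$stage1, tot / n)
  }

  # ---- stage 2: heads only, embedding frozen
  opt <- .adamInit(params)
  for (ep in seq_len(config$epochs2)) {
    tot <- 0
    for (bt in batches()) {
      fw <- .modelForwardTrain(params, spec, X[bt, , drop = FALSE],
                               sampleZ = FALSE)
      down <- .downstreamLossGrads(params, spec, fw,
                                   .subsetTargets(targets, bt), W)
      grads <- list()
      for (tk in names(down$perTask))
        grads <- .accumulate(grads, down$perTask[[tk]]$grads,
                             W[[tk]] / K)
      st <- .adamStep(params, grads, opt, config$lr, only = headNames)
      params <- st$params; opt <- st$state
      loss <- jointDownstreamLoss(down$losses, W[names(down$losses)])
      tot <- tot + loss * length(bt)
    }
    .checkFinite(tot / n, 2L, ep)
    history$stage2 <- c(history$stage2, tot / n)
  }

  # ---- stage 3: joint fine-tune with GradNorm weight updates
  opt <- .adamInit(params)
  L0 <- NULL
  for (ep in seq_len(config$epochs3)) {
    tot <- 0
    for (bt in batches()) {
      Xb <- X[bt, , drop = FALSE]
      fw <- .modelForwardTrain(params, spec, Xb)
      eg <- .embedLossGrads(params, spec, fw, Xb, config$reconReduction)
      down <- .downstreamLossGrads(params, spec, fw,
                                   .subsetTargets(targets, bt), W)
      grads <- eg$grads
      dMuDown <- matrix(0, nrow(fw$mu), ncol(fw$mu))
      for (tk in names(down$perTask)) {
        grads <- .accumulate(grads, down$perTask[[tk]]$grads, W[[tk]] / K)
        dMuDown <- dMuDown + down$perTask[[tk]]$dMu * (W[[tk]] / K)
      }
      # push the downstream gradient through mu into the encoder
      gradsMu <- list()
      bwMu <- .bwdLin(params, "mu", fw$H, dMuDown, gradsMu)
      grads <- .accumulate(grads, bwMu$grads)
      bwEnc <- .bwdStack(params, "enc", length(spec$hidden), fw$encActs,
                         bwMu$dX, list())
      grads <- .accumulate(grads, bwEnc$grads)

      if (config$gradnorm && K > 1) {
        connected <- vapply(down$perTask, `[[`, logical(1), "connected")
        if (all(connected)) {
          if (is.null(L0)) L0 <- pmax(down$losses, 1e-8)
          g <- .muLayerGradNorms(fw$H,
                                 lapply(down$perTask, `[[`, "dMu"))
          G <- W[names(g)] * g
          gn <- gradnormLoss(G, L0[names(g)], down$losses[names(g)],
                             config$alpha)
          dW <- sign(G - gn$targets) * g
          W <- updateTaskWeights(W, dW[names(W)], config$lrW)
        }
      }
      st <- .adamStep(params, grads, opt, config$lr)
      params <- st$params; opt <- st$state
      loss <- eg$loss + jointDownstreamLoss(down$losses,
                                            W[names(down$losses)])
      tot <- tot + loss * length(bt)
    }
    .checkFinite(tot / n, 3L, ep)
    history$stage3 <- c(history$stage3, tot / n)
    history$taskWeights <- rbind(history$taskWeights, W)
  }

  model@params <- params
  model@taskWeights <- W
  model@trained <- TRUE
  model@history <- history
  model
}

# rebuild the survival head output layer when the effective number of
# intervals differs from the requested one (tied-quantile collapse)
.resizeSurvivalHead <- function(model, m) {
  spec <- model@spec
  if (!"survival" %in% names(spec$heads)) return(model)
  spec$heads$survival$out <- as.integer(m)
  hw <- c(spec$latentDim, spec$heads$survival$hidden)
  l <- .initLinear(hw[length(hw)], m)
  model@params[["head.survivalOut.W"]] <- l$W
  model@params[["head.survivalOut.b"]] <- l$b
  model@spec <- spec
  model
}

#' Predict on new samples with a trained model
#'
#' Scales the input blocks with the training scalers, embeds them via the
#' latent posterior mean, and applies every task head: class probabilities
#' (softmax), onset-age predictions (de-standardized), per-sample MTLR
#' survival curves and risk scores.
#'
#' @param object a trained [MoalsModel-class].
#' @param blocks named list of [OmicsBlock-class] inputs with the model's
#'   features (same block names).
#' @param ... ignored.
#' @return list with (depending on the attached heads):
#'   \code{embedding} (mu), \code{classProb} (samples x classes),
#'   \code{classPred} (factor), \code{onset} (numeric),
#'   \code{survivalScores}, \code{survivalCurves} (samples x intervals),
#'   \code{risk} (numeric).
#' @export
predictMoals <- function(object, blocks, ...) {
  stopifnot(is(object, "MoalsModel"))
  spec <- object@spec
  stopifnot(identical(names(blocks), names(spec$blockDims)))
  ids <- sampleIDs(blocks[[1]])
  Xs <- lapply(names(blocks), function(nm)
    applyScaler(object@scalers[[nm]], blockValues(blocks[[nm]])))
  X <- do.call(cbind, Xs)
  post <- encode(object, X)
  mu <- post$mu
  out <- list(embedding = mu)
  for (tk in names(spec$heads)) {
    hs <- spec$heads[[tk]]
    acts <- .fwdStack(object@params, paste0("head.", tk),
                      length(hs$hidden), mu)
    o <- .fwdLin(object@params, paste0("head.", tk, "Out"),
                 acts[[length(hs$hidden) + 1L]])
    if (tk == "classification") {
      p <- .softmax(o)
      colnames(p) <- object@classLevels
      rownames(p) <- ids
      out$classProb <- p
      out$classPred <- factor(object@classLevels[max.col(p)],
                              levels = object@classLevels)
    } else if (tk == "regression") {
      out$onset <- setNames(o[, 1] * object@onsetScale[2] +
                              object@onsetScale[1], ids)
    } else if (tk == "survival") {
      rownames(o) <- ids
      out$survivalScores <- o
      out$survivalCurves <- t(apply(o, 1, predictSurvivalCurve,
                                    grid = object@timeGrid))
      out$risk <- setNames(
        apply(o, 1, riskScore, grid = object@timeGrid), ids)
    }
  }
  out
}

#' @describeIn predictMoals S4 method for \code{predict}.
#' @param newdata named list of [OmicsBlock-class] inputs.
#' @export
setMethod("predict", "MoalsModel",
          function(object, newdata, ...) predictMoals(object, newdata, ...))
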