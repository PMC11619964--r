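# MoalsModel construction and the forward/backward passes that tie the
# VAE embedding to the downstream task heads. Parameters live in one flat
# named list; component layouts are described by model@spec:
#   enc{i}.W/.b   encoder hidden layers (ReLU)
#   mu.W/.b       last encoding layer -> latent mean
#   lv.W/.b       last encoding layer -> latent half log-variance
#   dec{i}.W/.b   decoder hidden layers (ReLU, mirrored widths)
#   decOut.W/.b   decoder output layer (sigmoid)
#   head.{task}{i}.W/.b, head.{task}Out.W/.b  task heads (from mu)

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize a MOALS multi-task model
#'
#' Builds the parameter set for a VAE over concatenated omics blocks with
#' mirrored encoder/decoder (ReLU hidden layers, sigmoid reconstruction
#' output) and one fully connected head per downstream task operating on
#' the latent mean. Defaults follow the reference hyperparameters: latent
#' dimension 128, hidden widths 512-256.
#'
#' @param blockDims named list/vector of per-block input widths, in
#'   concatenation order (e.g. \code{c(expression = 500, burden = 100)}).
#' @param latentDim latent dimension p (default 128).
#' @param hidden encoder hidden widths (decoder mirrors them).
#' @param tasks character subset of
#'   \code{c("classification", "regression", "survival")}.
#' @param headHidden hidden widths of every task head.
#' @param nClasses number of classes for the classification head.
#' @param mIntervals survival head width (number of time intervals).
#' @param seed integer seed for the parameter initialization.
#' @return an untrained [MoalsModel-class].
#' @export
moalsModel <- function(blockDims, latentDim = 128L, hidden = c(512L, 256L),
                       tasks = c("classification", "regression",
                                 "survival"),
                       headHidden = c(64L), nClasses = 2L,
                       mIntervals = 10L, seed = 1L) {
  stopifnot(latentDim >= 1, length(blockDims) >= 1)
  blockDims <- as.list(blockDims)
  tasks <- match.arg(tasks, several.ok = TRUE)
  heads <- list()
  for (tk in tasks)
    heads[[tk]] <- list(hidden = as.integer(headHidden),
                        out = switch(tk, classification = as.integer(nClasses),
                                     regression = 1L,
                                     survival = as.integer(mIntervals)))
  spec <- list(blockDims = blockDims, hidden = as.integer(hidden),
               latentDim = as.integer(latentDim), heads = heads)

  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))

  D <- sum(unlist(blockDims))
  params <- list()
  widths <- c(D, spec$hidden)
  for (i in seq_along(spec$hidden)) {
    l <- .initLinear(widths[i], widths[i + 1])
    params[[paste0("enc", i, ".W")]] <- l$W
    params[[paste0("enc", i, ".b")]] <- l$b
  }
  hTop <- widths[length(widths)]
  for (nm in c("mu", "lv")) {
    l <- .initLinear(hTop, spec$latentDim)
    params[[paste0(nm, ".W")]] <- l$W
    params[[paste0(nm, ".b")]] <- l$b
  }
  dWidths <- c(spec$latentDim, rev(spec$hidden))
  for (i in seq_along(rev(spec$hidden))) {
    l <- .initLinear(dWidths[i], dWidths[i + 1])
    params[[paste0("dec", i, ".W")]] <- l$W
    params[[paste0("dec", i, ".b")]] <- l$b
  }
  l <- .initLinear(dWidths[length(dWidths)], D)
  params[["decOut.W"]] <- l$W
  params[["decOut.b"]] <- l$b
  for (tk in names(heads)) {
    hw <- c(spec$latentDim, heads[[tk]]$hidden)
    for (i in seq_along(heads[[tk]]$hidden)) {
      l <- .initLinear(hw[i], hw[i + 1])
      params[[paste0("head.", tk, i, ".W")]] <- l$W
      params[[paste0("head.", tk, i, ".b")]] <- l$b
    }
    l <- .initLinear(hw[length(hw)], heads[[tk]]$out)
    params[[paste0("head.", tk, "Out.W")]] <- l$W
    params[[paste0("head.", tk, "Out.b")]] <- l$b
  }
  w <- setNames(rep(1, length(heads)), names(heads))
  new("MoalsModel", spec = spec, params = params, taskWeights = w,
      scalers = list(), timeGrid = new("TimeGrid", boundaries = c(0, 1)),
      classLevels = character(), onsetScale = c(0, 1),
      seed = as.integer(seed), trained = FALSE, history = list())
}

.paramNames <- function(spec, component = c("embedding", "heads")) {
  component <- match.arg(component)
  nE <- length(spec$hidden)
  if (component == "embedding") {
    nms <- c(if (nE) paste0("enc", seq_len(nE)), "mu", "lv",
             if (nE) paste0("dec", seq_len(nE)), "decOut")
  } else {
    nms <- unlist(lapply(names(spec$heads), function(tk)
      c(if (length(spec$heads[[tk]]$hidden))
          paste0("head.", tk, seq_along(spec$heads[[tk]]$hidden)),
        paste0("head.", tk, "Out"))))
  }
  as.vector(outer(nms, c(".W", ".b"), paste0))
}

# full forward pass used in training; sampleZ = FALSE makes z = mu
.modelForwardTrain <- function(params, spec, X, eps = NULL,
                               sampleZ = TRUE) {
  nE <- length(spec$hidden)
  encActs <- .fwdStack(params, "enc", nE, X)
  H <- encActs[[nE + 1L]]
  mu <- .fwdLin(params, "mu", H)
  logvar <- .fwdLin(params, "lv", H)
  sigma <- exp(0.5 * logvar)
  if (!sampleZ) {
    eps <- matrix(0, nrow(mu), ncol(mu))
  } else if (is.null(eps)) {
    eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  z <- mu + sigma * eps
  decActs <- .fwdStack(params, "dec", nE, z)
  U <- .fwdLin(params, "decOut", decActs[[nE + 1L]])
  xhat <- .sigmoid(U)
  list(encActs = encActs, H = H, mu = mu, logvar = logvar, sigma = sigma,
       eps = eps, z = z, decActs = decActs, xhat = xhat)
}

.blockColumnIndex <- function(spec) {
  dims <- unlist(spec$blockDims)
  ends <- cumsum(dims)
  starts <- c(1L, head(ends, -1L) + 1L)
  stats::setNames(mapply(seq, starts, ends, SIMPLIFY = FALSE), names(dims))
}

# embedding loss value + gradients w.r.t. all embedding params.
# reduction = "sum": per-block BCE is the Bernoulli log-likelihood summed
# over the block's features (the ELBO reconstruction term), averaged over
# blocks and batch — the training default, which keeps reconstruction and
# KL on comparable scales. reduction = "mean" averages over elements
# within the block (the embeddingLoss() interface contract).
.embedLossGrads <- function(params, spec, fw, X, reduction = "sum") {
  B <- nrow(X)
  M <- length(spec$blockDims)
  cols <- .blockColumnIndex(spec)
  xhatC <- pmin(pmax(fw$xhat, .BCE_CLIP), 1 - .BCE_CLIP)
  bceEl <- -(X * log(xhatC) + (1 - X) * log(1 - xhatC))
  bces <- vapply(cols, function(cc) {
    bb <- bceEl[, cc, drop = FALSE]
    if (reduction == "sum") sum(bb) / B else mean(bb)
  }, numeric(1))
  kl <- mean(rowSums(fw$mu^2 + fw$sigma^2 - 1 - fw$logvar)) / 2
  loss <- mean(bces) + kl

  wCol <- numeric(ncol(X))
  for (j in seq_along(cols)) {
    nj <- if (reduction == "sum") 1L else length(cols[[j]])
    wCol[cols[[j]]] <- 1 / (M * nj * B)
  }
  dU <- (fw$xhat - X) * rep(wCol, each = B)

  grads <- list()
  nE <- length(spec$hidden)
  bw <- .bwdLin(params, "decOut", fw$decActs[[nE + 1L]], dU, grads)
  grads <- bw$grads
  bw <- .bwdStack(params, "dec", nE, fw$decActs, bw$dX, grads)
  grads <- bw$grads
  dz <- bw$dX
  dMu <- dz + fw$mu / B
  dLv <- 0.5 * dz * fw$eps * fw$sigma + 0.5 * (fw$sigma^2 - 1) / B
  bwMu <- .bwdLin(params, "mu", fw$H, dMu, grads)
  grads <- bwMu$grads
  bwLv <- .bwdLin(params, "lv", fw$H, dLv, grads)
  grads <- bwLv$grads
  dH <- bwMu$dX + bwLv$dX
  bw <- .bwdStack(params, "enc", nE, fw$encActs, dH, grads)
  list(loss = loss, grads = bw$grads)
}

# per-task unweighted losses, head-parameter gradients, and dL_k/dMu
.downstreamLossGrads <- function(params, spec, fw, targets, weights) {
  perTask <- list()
  B <- nrow(fw$mu)
  for (tk in names(spec$heads)) {
    hs <- spec$heads[[tk]]
    nH <- length(hs$hidden)
    acts <- .fwdStack(params, paste0("head.", tk), nH, fw$mu)
    out <- .fwdLin(params, paste0("head.", tk, "Out"), acts[[nH + 1L]])
    tg <- targets[[tk]]
    res <- switch(tk,
      classification = .classLossGrad(out, tg),
      regression = .regLossGrad(out, tg),
      survival = .survLossGrad(out, tg))
    grads <- list()
    bw <- .bwdLin(params, paste0("head.", tk, "Out"), acts[[nH + 1L]],
                  res$dOut, grads)
    grads <- bw$grads
    bw <- .bwdStack(params, paste0("head.", tk), nH, acts, bw$dX, grads)
    perTask[[tk]] <- list(loss = res$loss, grads = bw$grads, dMu = bw$dX,
                          connected = res$connected, out = out)
  }
  list(perTask = perTask,
       losses = vapply(perTask, `[[`, numeric(1), "loss"))
}

.classLossGrad <- function(out, tg) {
  y <- tg$y
  valid <- which(!is.na(y))
  dOut <- matrix(0, nrow(out), ncol(out))
  if (!length(valid))
    return(list(loss = 0, dOut = dOut, connected = FALSE))
  p <- .softmax(out[valid, , drop = FALSE])
  onehot <- matrix(0, length(valid), ncol(out))
  onehot[cbind(seq_along(valid), y[valid])] <- 1
  if (is.null(tg$classWeights)) {
    w <- rep(1, length(valid))
  } else w <- tg$classWeights[y[valid]]
  wSum <- sum(w)
  ll <- -log(pmax(p[cbind(seq_along(valid), y[valid])], 1e-300))
  dOut[valid, ] <- (p - onehot) * (w / wSum)
  list(loss = sum(w * ll) / wSum, dOut = dOut, connected = TRUE)
}

.regLossGrad <- function(out, tg) {
  y <- tg$y
  valid <- which(!is.na(y))
  dOut <- matrix(0, nrow(out), ncol(out))
  if (!length(valid))
    return(list(loss = 0, dOut = dOut, connected = FALSE))
  err <- out[valid, 1] - y[valid]
  dOut[valid, 1] <- 2 * err / length(valid)
  list(loss = mean(err^2), dOut = dOut, connected = TRUE)
}

.survLossGrad <- function(out, tg) {
  ev <- tg$event
  iv <- tg$interval
  valid <- which(!is.na(ev))
  m <- ncol(out)
  dOut <- matrix(0, nrow(out), m)
  if (!length(valid))
    return(list(loss = 0, dOut = dOut, connected = FALSE))
  losses <- numeric(length(valid))
  for (idx in seq_along(valid)) {
    i <- valid[idx]
    s <- .suffixScores(out[i, ])            # j = 0..m at index j+1
    logZ <- .logSumExp(s)
    P <- exp(s - logZ)
    q <- numeric(m + 1L)
    if (ev[i] == 1) {
      q[iv[i]] <- 1                          # config j = interval - 1
      losses[idx] <- logZ - s[iv[i]]
    } else {
      compat <- seq.int(iv[i], m + 1L)       # configs j >= interval - 1
      q[compat] <- P[compat] / sum(P[compat])
      losses[idx] <- logZ - .logSumExp(s[compat])
    }
    dOut[i, ] <- cumsum(P - q)[seq_len(m)] / length(valid)
  }
  list(loss = mean(losses), dOut = dOut, connected = TRUE)
}

.accumulate <- function(total, add, scale = 1) {
  for (k in names(add)) {
    total[[k]] <- if (is.null(total[[k]])) add[[k]] * scale
                  else total[[k]] + add[[k]] * scale
  }
  total
}

# scale + concatenate aligned blocks and build per-task targets
.prepareBatchData <- function(model, blocks, sampleTable,
                              classWeights = NULL) {
  spec <- model@spec
  stopifnot(identical(names(blocks), names(spec$blockDims)))
  Xs <- lapply(names(blocks), function(nm)
    applyScaler(model@scalers[[nm]], blockValues(blocks[[nm]])))
  X <- do.call(cbind, Xs)
  stopifnot(identical(rownames(X), sampleTable$sample))
  targets <- list()
  if ("classification" %in% names(spec$heads)) {
    y <- match(as.character(sampleTable$label), model@classLevels)
    targets$classification <- list(y = y, classWeights = classWeights)
  }
  if ("regression" %in% names(spec$heads)) {
    y <- (sampleTable$onset_age - model@onsetScale[1]) / model@onsetScale[2]
    targets$regression <- list(y = y)
  }
  if ("survival" %in% names(spec$heads)) {
    tt <- sampleTable$time
    ev <- sampleTable$event
    iv <- rep(NA_integer_, length(tt))
    ok <- !is.na(tt) & !is.na(ev)
    if (any(ok))
      iv[ok] <- suppressWarnings(
        vapply(tt[ok], .intervalOf, integer(1), grid = model@timeGrid))
    ev[!ok] <- NA
    targets$survival <- list(event = ev, interval = iv)
  }
  list(X = X, targets = targets)
}

.subsetTargets <- function(targets, idx) {
  lapply(targets, function(tg) {
    tg2 <- tg
    for (f in intersect(names(tg), c("y", "event", "interval")))
      tg2[[f]] <- tg[[f]][idx]
    tg2
  })
}
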