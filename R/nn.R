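# Minimal dense-network toolkit: parameter initialization, forward and
# backward passes for stacks of ReLU layers, and an Adam optimizer. All
# parameters live in one flat named list of matrices (W, in x out) and
# vectors (b), so freezing, copying and norm computations are trivial.

.initLinear <- function(nin, nout) {
  # Glorot-uniform
  lim <- sqrt(6 / (nin + nout))
  list(W = matrix(runif(nin * nout, -lim, lim), nin, nout),
       b = rep(0, nout))
}

.relu <- function(x) pmax(x, 0)

.fwdLin <- function(params, name, X) {
  X %*% params[[paste0(name, ".W")]] +
    rep(params[[paste0(name, ".b")]], each = nrow(X))
}

.bwdLin <- function(params, name, X, dOut, grads) {
  grads[[paste0(name, ".W")]] <- crossprod(X, dOut)
  grads[[paste0(name, ".b")]] <- colSums(dOut)
  list(grads = grads, dX = dOut %*% t(params[[paste0(name, ".W")]]))
}

# forward through nLayers ReLU layers named {prefix}{i}; returns the list
# of activations (acts[[1]] = input, acts[[i+1]] = output of layer i)
.fwdStack <- function(params, prefix, nLayers, X) {
  acts <- vector("list", nLayers + 1L)
  acts[[1L]] <- X
  for (i in seq_len(nLayers))
    acts[[i + 1L]] <- .relu(.fwdLin(params, paste0(prefix, i), acts[[i]]))
  acts
}

# backward through the same stack given dTop = dL/d(acts[[nLayers+1]])
.bwdStack <- function(params, prefix, nLayers, acts, dTop, grads) {
  d <- dTop
  for (i in rev(seq_len(nLayers))) {
    d <- d * (acts[[i + 1L]] > 0)          # ReLU gate
    bw <- .bwdLin(params, paste0(prefix, i), acts[[i]], d, grads)
    grads <- bw$grads
    d <- bw$dX
  }
  list(grads = grads, dX = d)
}

.zeroLike <- function(params) lapply(params, function(p) p * 0)

.adamInit <- function(params) {
  list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, only = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  keys <- if (is.null(only)) names(grads) else intersect(only, names(grads))
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in keys) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
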