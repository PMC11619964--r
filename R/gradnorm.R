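# GradNorm-balanced joint downstream loss:
#   L_down = (1/K) sum_k W_k L_k
#   G(k)   = || grad_theta (W_k L_k) ||_2   (theta = last encoding layer)
#   r_k    = (L_k / L0_k) / mean_k(L_k / L0_k)
#   L_grad = sum_k | G(k) - Gbar r_k^alpha |
# A separate update step on L_grad adjusts only the task weights W_k,
# which are renormalized to sum to K after every step.

#' Weighted joint downstream loss
#'
#' \eqn{L_{down} = \frac{1}{K} \sum_k W_k L_k}.
#'
#' @param taskLosses numeric vector of per-task losses.
#' @param weights matching numeric vector of task weights W_k.
#' @return scalar.
#' @export
jointDownstreamLoss <- function(taskLosses, weights) {
  if (length(taskLosses) != length(weights))
    stop("taskLosses and weights must have equal length")
  mean(weights * taskLosses)
}

#' GradNorm balancing loss
#'
#' Computes the targets \eqn{\bar{G} r_k^\alpha} from the relative inverse
#' training rates \eqn{r_k = \tilde{L}_k / \mathrm{mean}(\tilde{L})},
#' \eqn{\tilde{L}_k = L_k / L^0_k}, and returns
#' \eqn{L_{grad} = \sum_k |G(k) - \bar{G} r_k^\alpha|}. The targets are
#' treated as constants (no gradient) in the weight update.
#'
#' @param G numeric vector of per-task gradient norms \eqn{G(k)} (already
#'   scaled by W_k).
#' @param initialLosses per-task losses at the start of joint training
#'   (must be positive).
#' @param currentLosses current per-task losses.
#' @param alpha balancing strength hyperparameter (default 1.5).
#' @return list with \code{loss}, \code{targets}, \code{rates} (r_k).
#' @export
gradnormLoss <- function(G, initialLosses, currentLosses, alpha = 1.5) {
  K <- length(G)
  stopifnot(length(initialLosses) == K, length(currentLosses) == K)
  if (any(initialLosses <= 0)) stop("initial losses must be positive")
  Ltilde <- currentLosses / initialLosses
  r <- Ltilde / mean(Ltilde)
  targets <- mean(G) * r^alpha
  list(loss = sum(abs(G - targets)), targets = targets, rates = r)
}

#' Update GradNorm task weights
#'
#' Applies one gradient step on \eqn{L_{grad}} with respect to the task
#' weights only (\eqn{\partial L_{grad} / \partial W_k =
#' \mathrm{sign}(G_k - \mathrm{target}_k)\, g_k} where \eqn{g_k} is the
#' unweighted gradient norm, since \eqn{G_k = W_k g_k}), clips any
#' non-positive weight to 1e-4 with a message, and renormalizes so
#' \eqn{\sum_k W_k = K}.
#'
#' @param weights named numeric vector of current W_k (> 0).
#' @param gradnormGradients \eqn{\partial L_{grad} / \partial W_k} per
#'   task.
#' @param lrW learning rate for the weight step.
#' @return updated weights, summing to K.
#' @export
updateTaskWeights <- function(weights, gradnormGradients, lrW = 0.025) {
  stopifnot(length(weights) == length(gradnormGradients))
  w <- weights - lrW * gradnormGradients
  if (any(w <= 0)) {
    message("clipping non-positive task weight(s) to 1e-4")
    w[w <= 0] <- 1e-4
  }
  w * length(w) / sum(w)
}

# Per-task gradient norms at the last encoding layer (the mu-producing
# linear layer): given per-task gradients of the UNWEIGHTED losses w.r.t.
# mu, returns g_k = ||grad_theta L_k||. G_k = W_k g_k by linearity.
.muLayerGradNorms <- function(H, dMuList) {
  vapply(dMuList, function(dMu) {
    gW <- crossprod(H, dMu)
    gb <- colSums(dMu)
    sqrt(sum(gW^2) + sum(gb^2))
  }, numeric(1))
}

#' Per-task gradient norms at the model's last encoding layer
#'
#' Computes \eqn{G_\theta(k) = \|\nabla_\theta W_k L_k\|_2} where
#' \eqn{\theta} are the parameters of the encoder's final (mu-producing)
#' layer, for each downstream task, on a given batch. Gradients are not
#' accumulated into any update. A task whose loss does not depend on the
#' embedding (no valid samples in the batch) is an error.
#'
#' @param model a [MoalsModel-class] with downstream heads.
#' @param blocks named list of [OmicsBlock-class] inputs (same layout the
#'   model was built for).
#' @param sampleTable aligned sample metadata.
#' @return named numeric vector of G(k) per task.
#' @export
taskGradientNorms <- function(model, blocks, sampleTable) {
  prep <- .prepareBatchData(model, blocks, sampleTable)
  fw <- .modelForwardTrain(model@params, model@spec, prep$X, sampleZ = FALSE)
  down <- .downstreamLossGrads(model@params, model@spec, fw,
                               prep$targets, model@taskWeights)
  if (any(!vapply(down$perTask, function(t) t$connected, logical(1))))
    stop("a task loss is detached from the embedding (no valid samples)")
  g <- .muLayerGradNorms(fw$H, lapply(down$perTask, `[[`, "dMu"))
  model@taskWeights[names(g)] * g
}
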