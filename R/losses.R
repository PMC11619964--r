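# Downstream task losses: cross-entropy classification and mean-squared
# error regression.

#' Cross-entropy classification loss
#'
#' \eqn{L = -\log \mathrm{softmax}(\mathrm{logits})[y]}, averaged over the
#' batch. Optional per-class weights (e.g. inverse class frequencies for
#' imbalanced cohorts) reweight each sample by its true-class weight and
#' normalize by the total weight.
#'
#' @param yTrue integer vector of true class indices (1-based), or a
#'   factor.
#' @param yLogits samples x classes matrix of unnormalized scores (a
#'   single numeric vector is treated as one sample).
#' @param classWeights optional numeric vector of per-class weights.
#' @return scalar loss.
#' @examples
#' classificationLoss(1L, c(1, 0))  # -log(e / (e + 1)) ~ 0.3133
#' @export
classificationLoss <- function(yTrue, yLogits, classWeights = NULL) {
  if (!is.matrix(yLogits)) yLogits <- matrix(yLogits, nrow = 1)
  if (is.factor(yTrue)) yTrue <- as.integer(yTrue)
  yTrue <- as.integer(yTrue)
  if (any(yTrue < 1L | yTrue > ncol(yLogits)))
    stop("label outside the class set")
  p <- .softmax(yLogits)
  ll <- -log(pmax(p[cbind(seq_along(yTrue), yTrue)], 1e-300))
  if (is.null(classWeights)) return(mean(ll))
  w <- classWeights[yTrue]
  sum(w * ll) / sum(w)
}

#' Mean-squared-error regression loss
#'
#' Mean of squared differences between observed and predicted values over
#' the batch.
#'
#' @param yTrue,yPred finite numeric vectors of equal length.
#' @return scalar loss.
#' @export
regressionLoss <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred),
            all(is.finite(yTrue)), all(is.finite(yPred)))
  mean((yTrue - yPred)^2)
}
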