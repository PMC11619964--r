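# Variational-autoencoder primitives: the Gaussian encoder posterior, the
# reparameterization trick, the closed-form Gaussian KL divergence, and
# the per-omics-averaged embedding loss
#   L_embed = (1/M) sum_j BCE(x_j, x_j') + KL(N(mu, sigma) || N(0, I)).

.BCE_CLIP <- 1e-7

#' Encode inputs to the Gaussian latent posterior
#'
#' Runs the encoder stack of a [MoalsModel-class] on already-scaled,
#' concatenated omics inputs and returns the posterior parameters. The
#' standard deviation is produced through a strictly positive link,
#' \code{sigma = exp(0.5 logvar)}, from a half log-variance output head.
#' Deterministic given parameters and input.
#'
#' @param model a [MoalsModel-class].
#' @param x samples x totalFeatures numeric matrix in [0, 1], column
#'   layout matching the model's concatenated blocks.
#' @return list with matrices \code{mu}, \code{logvar}, \code{sigma}
#'   (samples x latentDim).
#' @export
encode <- function(model, x) {
  stopifnot(is(model, "MoalsModel"))
  x <- as.matrix(x)
  D <- sum(unlist(model@spec$blockDims))
  if (ncol(x) != D)
    stop(sprintf("input width %d does not match model width %d",
                 ncol(x), D))
  acts <- .fwdStack(model@params, "enc", length(model@spec$hidden), x)
  H <- acts[[length(acts)]]
  mu <- .fwdLin(model@params, "mu", H)
  logvar <- .fwdLin(model@params, "lv", H)
  list(mu = mu, logvar = logvar, sigma = exp(0.5 * logvar))
}

#' Reparameterized latent sample
#'
#' \eqn{z = \mu + \sigma \odot \epsilon}, \eqn{\epsilon \sim N(0, I)}.
#' \code{eps} can be injected for deterministic tests; when `NULL` it is
#' drawn from the current RNG.
#'
#' @param mu,sigma posterior mean and sd (vectors or matrices of one
#'   shape).
#' @param eps optional noise of the same shape.
#' @return z of the same shape.
#' @export
reparameterize <- function(mu, sigma, eps = NULL) {
  if (is.null(eps)) {
    eps <- if (is.matrix(mu))
      matrix(rnorm(length(mu)), nrow(mu), ncol(mu)) else rnorm(length(mu))
  }
  mu + sigma * eps
}

#' Closed-form Gaussian KL divergence to the standard normal prior
#'
#' \deqn{KL = \tfrac{1}{2}\sum_d (\mu_d^2 + \sigma_d^2 - 1 -
#'   \ln \sigma_d^2) \ge 0,} with equality iff \eqn{\mu = 0, \sigma = 1}.
#' For a matrix input (samples x latent dims) the per-sample KLs are
#' averaged.
#'
#' @param mu posterior mean vector, or samples x dims matrix.
#' @param sigma posterior sd, strictly positive, same shape.
#' @return scalar KL (batch mean for matrix input).
#' @export
klClosedForm <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  term <- mu^2 + sigma^2 - 1 - 2 * log(sigma)
  if (is.matrix(mu)) mean(rowSums(term)) / 2 else sum(term) / 2
}

.bceMean <- function(x, xhat) {
  xhat <- pmin(pmax(xhat, .BCE_CLIP), 1 - .BCE_CLIP)
  -mean(x * log(xhat) + (1 - x) * log(1 - xhat))
}

#' Embedding loss of the deep embedding module
#'
#' \deqn{L_{embed} = \frac{1}{M}\sum_{j=1}^{M} BCE(x_j, x_j') + KL,}
#' where the binary cross-entropy of block j is averaged over that block's
#' elements and M is the number of omics blocks. Inputs must be in [0, 1]
#' (see [fitMinmaxScaler()]); reconstructions must lie in (0, 1), as
#' produced by a sigmoid decoder output.
#'
#' @param blocksX list of M matrices (samples x features_j) in [0, 1].
#' @param blocksXRecon list of matching reconstruction matrices in (0, 1).
#' @param mu,sigma latent posterior parameters for the same samples.
#' @return scalar loss (batch mean).
#' @export
embeddingLoss <- function(blocksX, blocksXRecon, mu, sigma) {
  stopifnot(length(blocksX) == length(blocksXRecon),
            length(blocksX) >= 1)
  for (j in seq_along(blocksX)) {
    r <- blocksXRecon[[j]]
    if (any(r <= 0) || any(r >= 1))
      stop("reconstructions must lie strictly inside (0, 1)")
    x <- blocksX[[j]]
    if (any(x < 0) || any(x > 1))
      stop("inputs must lie in [0, 1]")
  }
  bces <- mapply(.bceMean, blocksX, blocksXRecon)
  mean(bces) + klClosedForm(mu, sigma)
}
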