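# Per-feature min-max scaling to [0, 1], fitted on training samples only.
# Required because the embedding reconstruction loss is a binary
# cross-entropy, which needs inputs in the unit interval.

#' Fit a per-feature min-max scaler on training samples
#'
#' Learns per-feature minima and maxima over the declared training samples
#' only (so test folds never leak into the scaling), mapping training data
#' into [0, 1]. A constant feature is mapped to 0.5. At transform time,
#' values outside the training range are clipped into [0, 1].
#'
#' @param block an [OmicsBlock-class].
#' @param trainingSampleIds character vector, non-empty subset of the
#'   block's samples.
#' @param transform optional pre-transform applied before the min/max are
#'   learned: \code{"identity"} or \code{"log1p"}. Heavy-tailed abundance
#'   data (e.g. log-normal expression) is best scaled on the log scale, so
#'   the unit interval is not dominated by a few extreme values.
#' @return a scaler state list (class \code{moalsScaler}) with fields
#'   \code{min}, \code{max}, \code{features}, \code{transform}.
#' @seealso [applyScaler()]
#' @export
fitMinmaxScaler <- function(block, trainingSampleIds = sampleIDs(block),
                            transform = c("identity", "log1p")) {
  transform <- match.arg(transform)
  v <- blockValues(block)
  if (transform == "log1p") v <- log1p(v)
  if (!length(trainingSampleIds))
    stop("trainingSampleIds must be non-empty")
  miss <- setdiff(trainingSampleIds, rownames(v))
  if (length(miss))
    stop(sprintf("training ids not in block: %s",
                 paste(head(miss, 3), collapse = ", ")))
  tr <- v[trainingSampleIds, , drop = FALSE]
  st <- list(min = apply(tr, 2, min), max = apply(tr, 2, max),
             features = colnames(v), transform = transform)
  class(st) <- "moalsScaler"
  st
}

#' Apply a fitted min-max scaler
#'
#' @param scaler a scaler state from [fitMinmaxScaler()].
#' @param values samples x features matrix with the scaler's features.
#' @return matrix of the same shape with all entries in [0, 1]; constant
#'   training features map to 0.5, out-of-range values are clipped.
#' @export
applyScaler <- function(scaler, values) {
  stopifnot(inherits(scaler, "moalsScaler"))
  values <- values[, scaler$features, drop = FALSE]
  if (identical(scaler$transform, "log1p")) values <- log1p(values)
  rng <- scaler$max - scaler$min
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(values, 2, scaler$min), 2, rng, "/")
  out[, const] <- 0.5
  pmin(pmax(out, 0), 1)
}
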