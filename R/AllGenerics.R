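# Accessor generics + show methods for the core S4 classes.

#' Accessors for MOALS objects
#'
#' @param x an object.
#' @return \code{blockName}: the layer label; \code{sampleIDs} /
#'   \code{featureIDs}: ordered identifier vectors; \code{blockValues}: the
#'   samples x features matrix; \code{membership} / \code{centroids} /
#'   \code{objectiveTrace} / \code{isConverged}: components of a
#'   [FuzzyClustering-class]; \code{geneSets}: the named list inside a
#'   [GeneSetCollection-class]; \code{boundaries}: the time-grid boundary
#'   vector; \code{nIntervals}: the number of intervals.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))
#' @rdname accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))

#' @rdname accessors
setMethod("blockName", "OmicsBlock", function(x) x@blockName)
#' @rdname accessors
setMethod("sampleIDs", "OmicsBlock", function(x) rownames(x@values))
#' @rdname accessors
setMethod("featureIDs", "OmicsBlock", function(x) colnames(x@values))
#' @rdname accessors
setMethod("blockValues", "OmicsBlock", function(x) x@values)

#' @rdname accessors
setMethod("membership", "FuzzyClustering", function(x) x@membership)
#' @rdname accessors
setMethod("centroids", "FuzzyClustering", function(x) x@centroids)
#' @rdname accessors
setMethod("objectiveTrace", "FuzzyClustering", function(x) x@objective)
#' @rdname accessors
setMethod("isConverged", "FuzzyClustering", function(x) x@converged)

#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname accessors
setMethod("boundaries", "TimeGrid", function(x) x@boundaries)
#' @rdname accessors
setMethod("nIntervals", "TimeGrid", function(x) length(x@boundaries) - 1L)

setMethod("show", "OmicsBlock", function(object) {
  v <- object@values
  cat(sprintf("OmicsBlock '%s': %d samples x %d features\n",
              object@blockName, nrow(v), ncol(v)))
  if (nrow(v) && ncol(v))
    cat(sprintf("  samples: %s%s\n  features: %s%s\n",
      paste(head(rownames(v), 3), collapse = ", "),
      if (nrow(v) > 3) ", ..." else "",
      paste(head(colnames(v), 3), collapse = ", "),
      if (ncol(v) > 3) ", ..." else ""))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d sets\n", length(object@sets)))
  for (nm in head(names(object@sets), 5))
    cat(sprintf("  %s (%d genes)\n", nm, length(object@sets[[nm]])))
  if (length(object@sets) > 5) cat("  ...\n")
})

setMethod("show", "FuzzyClustering", function(object) {
  cat(sprintf(
    "FuzzyClustering: %d points, c = %d, m = %.2f, %d iterations (%s)\n",
    nrow(object@membership), object@c, object@mFuzz,
    length(object@objective),
    if (object@converged) "converged" else "not converged"))
  cat(sprintf("  final objective J = %.6g\n",
              object@objective[length(object@objective)]))
})

setMethod("show", "TimeGrid", function(object) {
  b <- object@boundaries
  cat(sprintf("TimeGrid: %d intervals on [0, %.4g]\n", length(b) - 1L,
              b[length(b)]))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@samples$label)
  cat(sprintf(
    "SyntheticCohort: %d samples (%s), %d expression genes, %d burden genes\n",
    nrow(object@samples),
    paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
    ncol(object@expression@values), ncol(object@burden@values)))
})

setMethod("show", "MoalsModel", function(object) {
  s <- object@spec
  cat(sprintf("MoalsModel (%s)\n", if (object@trained) "trained"
              else "initialized"))
  cat(sprintf("  input: %s (total %d features)\n",
      paste(sprintf("%s[%d]", names(s$blockDims), unlist(s$blockDims)),
            collapse = " + "), sum(unlist(s$blockDims))))
  cat(sprintf("  encoder: %s -> latent %d; decoder mirrored\n",
      paste(s$hidden, collapse = "-"), s$latentDim))
  cat(sprintf("  heads: %s\n", paste(names(s$heads), collapse = ", ")))
  if (length(object@taskWeights))
    cat(sprintf("  task weights: %s\n",
        paste(sprintf("%s=%.3f", names(object@taskWeights),
                      object@taskWeights), collapse = ", ")))
})
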