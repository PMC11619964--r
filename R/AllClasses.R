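#' @import methods
#' @importFrom stats rnorm runif rbinom rpois rexp rlogis quantile median sd
#'   var phyper p.adjust setNames complete.cases qt aggregate uniroot plogis
#'   predict
#' @importFrom utils read.delim write.table head modifyList
NULL

#' OmicsBlock: one omics layer as a samples x features matrix
#'
#' A single omics layer of a cohort, stored in samples x features
#' orientation with unique, ordered sample and feature identifiers.
#' Expression blocks hold non-negative continuous abundances; burden blocks
#' hold non-negative (typically integer) per-gene rare-variant burden values.
#'
#' @slot blockName single character, e.g. \code{"expression"} or
#'   \code{"burden"}.
#' @slot values numeric matrix, samples in rows, features in columns, with
#'   complete dimnames.
#'
#' @seealso [OmicsBlock()] for the validated constructor,
#'   [readExpressionMatrix()] to load one from disk.
#' @exportClass OmicsBlock
setClass("OmicsBlock",
  representation(blockName = "character", values = "matrix"))

setValidity("OmicsBlock", function(object) {
  msgs <- character()
  v <- object@values
  if (length(object@blockName) != 1L || is.na(object@blockName) ||
      !nzchar(object@blockName))
    msgs <- c(msgs, "'blockName' must be a single non-empty string")
  if (!is.numeric(v))
    msgs <- c(msgs, "'values' must be a numeric matrix")
  if ((nrow(v) > 0 && is.null(rownames(v))) ||
      (ncol(v) > 0 && is.null(colnames(v))))
    msgs <- c(msgs, "'values' must have sample rownames and feature colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, sprintf("duplicate sample identifiers: %s",
        paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, sprintf("duplicate feature identifiers: %s",
        paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  if (is.numeric(v) && length(v) && !all(is.finite(v)))
    msgs <- c(msgs, "'values' must be finite")
  if (is.numeric(v) && length(v) && any(v < 0))
    msgs <- c(msgs, "'values' must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsBlock
#'
#' @param values numeric matrix (samples x features) with dimnames.
#' @param blockName label for the omics layer.
#' @return A validated [OmicsBlock-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("S1", "S2"), c("G1", "G2", "G3")))
#' OmicsBlock(m, "expression")
#' @export
OmicsBlock <- function(values, blockName = "expression") {
  storage.mode(values) <- "double"
  new("OmicsBlock", blockName = blockName, values = values)
}

#' GeneSetCollection: named gene sets (e.g. pathways from a GMT file)
#'
#' @slot sets named list of character vectors; each set is non-empty with no
#'   duplicated genes.
#' @slot descriptions named character vector of per-set descriptions.
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  s <- object@sets
  if (is.null(names(s)) || any(!nzchar(names(s))))
    msgs <- c(msgs, "all gene sets must be named")
  if (anyDuplicated(names(s)))
    msgs <- c(msgs, sprintf("duplicated set name: %s",
      paste(unique(names(s)[duplicated(names(s))]), collapse = ", ")))
  for (nm in names(s)) {
    if (!length(s[[nm]]))
      msgs <- c(msgs, sprintf("gene set '%s' is empty", nm))
    if (anyDuplicated(s[[nm]]))
      msgs <- c(msgs, sprintf("gene set '%s' contains duplicated genes", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' Duplicate genes within a set are collapsed; duplicate set names are an
#' error.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional character vector of descriptions, recycled
#'   against \code{sets}.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- setNames(rep_len(as.character(descriptions), length(sets)),
                           names(sets))
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' FuzzyClustering: result of fuzzy k-means on gene expression profiles
#'
#' Holds the soft partition of genes obtained by fuzzy k-means: centroids,
#' the genes x clusters membership matrix (rows sum to one), and the
#' objective trace \eqn{J = \sum_{ij} u_{ij}^m \|x_i - v_j\|^2} per
#' iteration, which is non-increasing for a correct fit.
#'
#' @slot c number of clusters.
#' @slot mFuzz fuzziness exponent (> 1).
#' @slot centroids c x features numeric matrix.
#' @slot membership genes x c matrix of membership degrees.
#' @slot objective numeric vector, objective value per iteration.
#' @slot converged logical, whether the centroid-displacement tolerance was
#'   reached before \code{maxIter}.
#' @slot seed integer seed used for centroid initialization.
#' @exportClass FuzzyClustering
setClass("FuzzyClustering",
  representation(c = "integer", mFuzz = "numeric", centroids = "matrix",
                 membership = "matrix", objective = "numeric",
                 converged = "logical", seed = "integer"))

setValidity("FuzzyClustering", function(object) {
  msgs <- character()
  U <- object@membership
  if (ncol(U) != object@c)
    msgs <- c(msgs, "membership must have c columns")
  if (length(U) && (any(U < -1e-12) || any(U > 1 + 1e-12)))
    msgs <- c(msgs, "membership degrees must lie in [0, 1]")
  if (length(U) && any(abs(rowSums(U) - 1) > 1e-9))
    msgs <- c(msgs, "membership rows must sum to 1 (within 1e-9)")
  if (nrow(object@centroids) != object@c)
    msgs <- c(msgs, "centroids must have c rows")
  if (length(object@objective) > 1 &&
      any(diff(object@objective) > 1e-8 * (1 + abs(object@objective[-1]))))
    msgs <- c(msgs, "objective trace must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' TimeGrid: discrete time intervals for MTLR survival modelling
#'
#' The time axis is split into m intervals \eqn{l_i = [t_{i-1}, t_i)} with
#' \eqn{t_0 = 0} and \eqn{t_m \ge \max(T)}. MTLR places one score on each
#' interval.
#'
#' @slot boundaries numeric vector \eqn{t_0 < t_1 < \dots < t_m}, with
#'   \code{boundaries[1] == 0}.
#' @exportClass TimeGrid
setClass("TimeGrid", representation(boundaries = "numeric"))

setValidity("TimeGrid", function(object) {
  b <- object@boundaries
  msgs <- character()
  if (length(b) < 2L) msgs <- c(msgs, "need at least one interval")
  if (length(b) && b[1] != 0) msgs <- c(msgs, "t0 must be 0")
  if (length(b) > 1 && any(diff(b) <= 0))
    msgs <- c(msgs, "boundaries must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticCohort: a simulated multi-omics cohort with planted truth
#'
#' Bundles the generated expression and burden blocks, the sample metadata
#' table, and the planted ground truth (latent factors, gene block
#' memberships, burden signal genes, per-sample log-hazard) used by
#' parameter-recovery tests.
#'
#' @slot expression [OmicsBlock-class] of log-normal expression values.
#' @slot burden [OmicsBlock-class] of Poisson burden counts.
#' @slot samples data.frame with columns \code{sample}, \code{label},
#'   \code{onset_age}, \code{time}, \code{event}.
#' @slot latent samples x latent factors matrix of the true drivers.
#' @slot geneBlocks named integer vector: planted co-expression block of each
#'   expression gene.
#' @slot signalGenes character vector of burden genes with case-linked rates.
#' @slot risk named numeric vector, true per-sample log-hazard linear
#'   predictor.
#' @slot config the [simulationConfig()] list the cohort was generated from.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(expression = "OmicsBlock", burden = "OmicsBlock",
                 samples = "data.frame", latent = "matrix",
                 geneBlocks = "integer", signalGenes = "character",
                 risk = "numeric", config = "list"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  ids <- object@samples$sample
  if (!identical(rownames(object@expression@values), ids) ||
      !identical(rownames(object@burden@values), ids) ||
      !identical(rownames(object@latent), ids))
    msgs <- c(msgs, "all components must share one sample order")
  if (length(msgs)) msgs else TRUE
})

#' MoalsModel: the trained (or initialized) multi-task deep embedding model
#'
#' Holds everything needed to embed and predict on new samples: the VAE
#' encoder/decoder parameters, per-task head parameters, GradNorm task
#' weights, per-block min-max scaler states, the survival time grid, the
#' class labels and onset-age normalization, and the training history.
#'
#' Parameters are stored in a flat named list of matrices/vectors
#' (\code{params}); the architecture (layer widths per component) lives in
#' \code{spec}. Use [moalsModel()] to initialize and [trainMoals()] to fit.
#'
#' @slot spec list describing the architecture (block widths, hidden widths,
#'   latent dimension, head layouts).
#' @slot params named list of weight matrices and bias vectors.
#' @slot taskWeights named numeric vector of GradNorm task weights W_k.
#' @slot scalers named list of per-block min-max scaler states.
#' @slot timeGrid [TimeGrid-class] used by the survival head (may be empty).
#' @slot classLevels character vector of class labels.
#' @slot onsetScale numeric c(center, scale) applied to onset ages.
#' @slot seed integer seed used for initialization.
#' @slot trained logical.
#' @slot history list of per-stage loss traces.
#' @exportClass MoalsModel
setClass("MoalsModel",
  representation(spec = "list", params = "list", taskWeights = "numeric",
                 scalers = "list", timeGrid = "TimeGrid",
                 classLevels = "character", onsetScale = "numeric",
                 seed = "integer", trained = "logical", history = "list"))
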