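# Local pathway-enrichment testing of fuzzy clusters and pathway-level
# gene selection. A cluster x gene-set overlap is tested with a one-sided
# hypergeometric upper-tail p-value against a declared background, and
# Benjamini-Hochberg adjustment is applied jointly across every
# cluster x set test.

#' Hypergeometric enrichment of clusters against gene sets
#'
#' For every (cluster, gene set) pair, tests whether the genes assigned to
#' the cluster (argmax membership) overlap the set more than expected by
#' chance, using the hypergeometric upper tail
#' \eqn{P(X \ge k)} with the cluster as the draw and the set (restricted to
#' the background) as the successes. Benjamini-Hochberg adjustment is
#' applied across all cluster x set tests jointly. A gene set disjoint from
#' the background yields p = 1 with a warning.
#'
#' @param clustering fitted [FuzzyClustering-class] of genes.
#' @param geneSets a [GeneSetCollection-class].
#' @param background character vector of background gene identifiers (the
#'   reference universe); must contain every clustered gene.
#' @return data.frame with one row per cluster x set: \code{cluster},
#'   \code{set}, \code{overlap} (k), \code{clusterSize} (n),
#'   \code{setSize} (successes in background), \code{background} (N),
#'   \code{pValue}, \code{fdr}.
#' @export
enrichClusters <- function(clustering, geneSets, background) {
  stopifnot(is(clustering, "FuzzyClustering"),
            is(geneSets, "GeneSetCollection"))
  ranked <- rankGenesByMembership(clustering)
  genes <- ranked$gene
  missing <- setdiff(genes, background)
  if (length(missing))
    stop(sprintf("background lacks %d clustered gene(s), e.g. %s",
                 length(missing), missing[1]))
  N <- length(unique(background))
  clusters <- sort(unique(ranked$cluster))
  sets <- geneSets(geneSets)
  res <- expand.grid(cluster = clusters, set = names(sets),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$overlap <- NA_integer_; res$clusterSize <- NA_integer_
  res$setSize <- NA_integer_; res$background <- N
  res$pValue <- NA_real_
  for (i in seq_len(nrow(res))) {
    clGenes <- ranked$gene[ranked$cluster == res$cluster[i]]
    setGenes <- intersect(sets[[res$set[i]]], background)
    if (!length(setGenes)) {
      warning(sprintf("gene set '%s' is disjoint from the background",
                      res$set[i]))
    }
    k <- length(intersect(clGenes, setGenes))
    n <- length(clGenes)
    K <- length(setGenes)
    res$overlap[i] <- k; res$clusterSize[i] <- n; res$setSize[i] <- K
    # upper tail P(X >= k); k = 0 gives p = 1
    res$pValue[i] <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  res$fdr <- p.adjust(res$pValue, method = "BH")
  res
}

#' Select genes from pathway-enriched clusters
#'
#' Returns the union of all genes assigned (argmax membership) to any
#' cluster whose BH-adjusted p-value against any of the target sets falls
#' below \code{fdrCutoff}. An empty selection is allowed.
#'
#' @param clustering fitted [FuzzyClustering-class].
#' @param enrichment result of [enrichClusters()] on this clustering.
#' @param targetSetNames character vector of target set names (e.g. the
#'   disease pathway of interest); an unknown name is a config error.
#' @param fdrCutoff FDR threshold, default 0.05.
#' @return character vector of selected gene identifiers (sorted).
#' @export
selectPathwayGenes <- function(clustering, enrichment, targetSetNames,
                               fdrCutoff = 0.05) {
  unknown <- setdiff(targetSetNames, unique(enrichment$set))
  if (length(unknown))
    stop(sprintf("unknown target set name(s): %s",
                 paste(unknown, collapse = ", ")))
  hits <- enrichment$set %in% targetSetNames & enrichment$fdr < fdrCutoff
  enrichedClusters <- unique(enrichment$cluster[hits])
  if (!length(enrichedClusters)) return(character(0))
  ranked <- rankGenesByMembership(clustering)
  sort(unique(ranked$gene[ranked$cluster %in% enrichedClusters]))
}

#' Pathway-level gene selection pipeline step
#'
#' Convenience wrapper chaining [standardizeGenes()], [fitFuzzyKmeans()],
#' [enrichClusters()] and [selectPathwayGenes()]: clusters the genes of an
#' expression block, tests every cluster against a gene-set collection,
#' and returns the genes of clusters enriched for the target sets.
#'
#' @param block expression [OmicsBlock-class].
#' @param geneSets [GeneSetCollection-class].
#' @param targetSetNames target pathway names.
#' @param c number of clusters.
#' @param mFuzz fuzziness exponent.
#' @param fdrCutoff FDR threshold.
#' @param background background universe; defaults to the clustered genes.
#' @param seed seed for the clustering initialization.
#' @return list with elements \code{genes} (selected identifiers),
#'   \code{clustering}, \code{enrichment}, \code{ranked}.
#' @export
selectGenes <- function(block, geneSets, targetSetNames, c = 8, mFuzz = 2,
                        fdrCutoff = 0.05, background = NULL, seed = 1) {
  X <- standardizeGenes(block)
  if (is.null(background)) background <- rownames(X)
  clustering <- fitFuzzyKmeans(X, c = c, mFuzz = mFuzz, seed = seed)
  enrichment <- enrichClusters(clustering, geneSets, background)
  genes <- selectPathwayGenes(clustering, enrichment, targetSetNames,
                              fdrCutoff)
  list(genes = genes, clustering = clustering, enrichment = enrichment,
       ranked = rankGenesByMembership(clustering))
}
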