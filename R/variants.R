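# Rare-variant prioritization: filtering, consequence-tier scoring, and
# aggregation into a per-sample gene-burden omics block.

#' Default consequence-tier score map
#'
#' High-impact coding consequences are prioritized in three tiers:
#' frameshift, stop-gained and transcript-ablation variants score 5;
#' stop-lost, start-lost and transcript-amplification variants score 3;
#' splice donor/acceptor variants score 2. Any other consequence term
#' scores 0 and is excluded from burden aggregation. The pairing of terms
#' to tiers follows the severity ordering of the prioritized classes and
#' is fully overridable.
#'
#' @return named integer vector mapping consequence terms to scores.
#' @examples
#' defaultConsequenceScores()[["frameshift_variant"]]  # 5
#' @export
defaultConsequenceScores <- function() {
  c(frameshift_variant = 5L, stop_gained = 5L, transcript_ablation = 5L,
    stop_lost = 3L, start_lost = 3L, transcript_amplification = 3L,
    splice_donor_variant = 2L, splice_acceptor_variant = 2L)
}

#' Filter annotated variants
#'
#' Keeps a record iff it is annotated to a canonical transcript AND carries
#' a recognized gene symbol AND its population allele frequency is below
#' \code{afCutoff} or is absent from population panels (`NA`). Order is
#' preserved and the operation is idempotent. A per-rule drop log is
#' attached as attribute \code{"filterLog"}: a record failing several
#' rules is attributed to the first failing rule, in the order canonical,
#' symbol, frequency.
#'
#' @param records variant data.frame from [readAnnotatedVariants()].
#' @param afCutoff rarity threshold on population allele frequency
#'   (default 0.01).
#' @return the qualifying subset of \code{records}, with attribute
#'   \code{filterLog} = named integer vector
#'   \code{c(canonical=, symbol=, frequency=)}.
#' @export
filterVariants <- function(records, afCutoff = 0.01) {
  okCanon <- records$canonical %in% TRUE
  okSymbol <- !is.na(records$gene) & nzchar(records$gene)
  okAf <- is.na(records$af) | records$af < afCutoff
  keep <- okCanon & okSymbol & okAf
  log <- c(canonical = sum(!okCanon),
           symbol = sum(okCanon & !okSymbol),
           frequency = sum(okCanon & okSymbol & !okAf))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filterLog") <- log
  out
}

#' Score a variant record by its consequence terms
#'
#' The score of a record is the maximum score over its annotated
#' consequence terms (terms are \code{&}-separated in VEP style); unknown
#' terms score 0.
#'
#' @param record one row of a variant data.frame, or any list with a
#'   \code{consequence} element.
#' @param scoreMap named integer vector, by default
#'   [defaultConsequenceScores()].
#' @return integer score.
#' @export
scoreVariant <- function(record, scoreMap = defaultConsequenceScores()) {
  terms <- strsplit(as.character(record$consequence), "&", fixed = TRUE)[[1]]
  scores <- scoreMap[terms]
  scores[is.na(scores)] <- 0L
  if (!length(scores)) 0L else as.integer(max(scores))
}

.scoreVariants <- function(records, scoreMap = defaultConsequenceScores()) {
  if (!nrow(records)) return(integer(0))
  vapply(strsplit(records$consequence, "&", fixed = TRUE), function(terms) {
    s <- scoreMap[terms]
    s[is.na(s)] <- 0L
    as.integer(max(c(s, 0L)))
  }, integer(1))
}

#' Aggregate filtered variants into a per-sample gene-burden block
#'
#' For \code{mode = "weighted"} (default) the burden of gene g in sample s
#' is the sum over that gene's qualifying records of
#' \code{score x allele count}; for \code{mode = "count"} it is the plain
#' allele-count sum over records with positive score. Variants scoring 0
#' under \code{scoreMap} never contribute, and genes with no qualifying
#' variant are dropped (all-zero columns removed).
#'
#' @param records filtered variant data.frame (see [filterVariants()]).
#' @param sampleIds character vector fixing the row set and order of the
#'   output; a record sample absent from it is an alignment error.
#' @param scoreMap consequence score map.
#' @param mode \code{"weighted"} or \code{"count"}.
#' @return An [OmicsBlock-class] named \code{"burden"} (samples x genes).
#' @export
buildGeneBurden <- function(records, sampleIds,
                            scoreMap = defaultConsequenceScores(),
                            mode = c("weighted", "count")) {
  mode <- match.arg(mode)
  scores <- .scoreVariants(records, scoreMap)
  keep <- scores > 0L
  records <- records[keep, , drop = FALSE]
  scores <- scores[keep]
  if (nrow(records)) {
    unknown <- setdiff(unique(records$sample), sampleIds)
    if (length(unknown))
      stop(sprintf("sample(s) in variant records but not in sample table: %s",
                   paste(unknown, collapse = ", ")))
  }
  genes <- sort(unique(records$gene))
  m <- matrix(0, nrow = length(sampleIds), ncol = length(genes),
              dimnames = list(sampleIds, genes))
  if (nrow(records)) {
    w <- if (mode == "weighted") scores * records$count else records$count
    agg <- rowsum(w, group = paste(records$sample, records$gene, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    si <- match(vapply(key, `[[`, "", 1L), sampleIds)
    gi <- match(vapply(key, `[[`, "", 2L), genes)
    m[cbind(si, gi)] <- agg[, 1]
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  OmicsBlock(m, blockName = "burden")
}
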