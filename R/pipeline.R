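# End-to-end pipeline: gene selection -> variant burden -> multi-task
# training -> cross-validated evaluation, with content-hash stage caching
# and one global seed from which every stage seed is derived.

#' Pipeline configuration
#'
#' Collects paths and stage sub-configurations for [runPipeline()]. Either
#' \code{variantPath} (annotated variants to be filtered/scored/aggregated)
#' or \code{burdenPath} (a precomputed burden matrix) may be given; with
#' neither, the model runs on expression only.
#'
#' @param exprPath expression matrix (genes in rows).
#' @param samplesPath sample metadata table.
#' @param gmtPath gene-set collection (GMT).
#' @param targetSets character vector of target pathway names.
#' @param variantPath optional VCF/TSV of annotated variants.
#' @param burdenPath optional precomputed burden TSV (samples in rows).
#' @param outDir output directory.
#' @param clusters,mFuzz,fdrCutoff gene-selection parameters.
#' @param scoreMode burden aggregation mode (\code{"weighted"} or
#'   \code{"count"}).
#' @param train a [moalsTrainConfig()].
#' @param folds cross-validation folds.
#' @param seed global seed; stage seeds derive from it.
#' @param verbose print progress messages.
#' @return list of class \code{moalsPipelineConfig}.
#' @export
pipelineConfig <- function(exprPath, samplesPath, gmtPath, targetSets,
                           variantPath = NULL, burdenPath = NULL,
                           outDir = "moals_out", clusters = 8L, mFuzz = 2,
                           fdrCutoff = 0.05, scoreMode = "weighted",
                           train = moalsTrainConfig(), folds = 5L,
                           seed = 1L, verbose = TRUE) {
  structure(list(exprPath = exprPath, samplesPath = samplesPath,
                 gmtPath = gmtPath, targetSets = targetSets,
                 variantPath = variantPath, burdenPath = burdenPath,
                 outDir = outDir, clusters = as.integer(clusters),
                 mFuzz = mFuzz, fdrCutoff = fdrCutoff,
                 scoreMode = scoreMode, train = train,
                 folds = as.integer(folds), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "moalsPipelineConfig")
}

.plog <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(fmt, ...))
}

.stageHash <- function(inputs, params) {
  files <- inputs[file.exists(inputs)]
  h <- unname(tools::md5sum(files))
  paste(c(h, utils::capture.output(utils::str(params))), collapse = "|")
}

.stageCached <- function(cfg, stage, hash, outputs) {
  cacheFile <- file.path(cfg$outDir, sprintf(".cache_%s", stage))
  if (file.exists(cacheFile) && all(file.exists(outputs)) &&
      identical(readLines(cacheFile, warn = FALSE), hash)) {
    .plog(cfg, "[%s] inputs unchanged, reusing cached outputs", stage)
    return(TRUE)
  }
  FALSE
}

.stageDone <- function(cfg, stage, hash) {
  writeLines(hash, file.path(cfg$outDir, sprintf(".cache_%s", stage)))
}

#' Run the full pipeline
#'
#' Executes gene selection, variant-burden construction, and
#' cross-validated multi-task training/evaluation in order, writing all
#' artifacts under \code{config$outDir}: \code{selected_genes.txt},
#' \code{enrichment.tsv}, \code{burden.tsv}, \code{fold_metrics.tsv},
#' \code{metrics.json}, \code{model.rds}, and the resolved configuration
#' snapshot \code{config.rds}. Stages whose inputs (content-hashed) and
#' parameters are unchanged are skipped and their cached outputs reused.
#' If no cluster passes the enrichment cutoff, the run falls back to the
#' full expression matrix with a message.
#'
#' @param config a [pipelineConfig()].
#' @return list with \code{selectedGenes}, \code{evaluation} (the
#'   [crossValidate()] result), \code{metrics} (pooled metric list), and
#'   \code{outDir}; identical metrics across reruns with the same global
#'   seed.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "moalsPipelineConfig"))
  cfg <- config
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  expr <- readExpressionMatrix(cfg$exprPath, orientation = "genes_in_rows")
  samples <- readSampleTable(cfg$samplesPath)

  # ---- stage: select-genes
  selFile <- file.path(cfg$outDir, "selected_genes.txt")
  enrFile <- file.path(cfg$outDir, "enrichment.tsv")
  selHash <- .stageHash(c(cfg$exprPath, cfg$gmtPath),
                        list(cfg$clusters, cfg$mFuzz, cfg$fdrCutoff,
                             cfg$targetSets, cfg$seed))
  if (!.stageCached(cfg, "select", selHash, c(selFile, enrFile))) {
    .plog(cfg, "[select] fuzzy k-means with c = %d", cfg$clusters)
    gmt <- readGmt(cfg$gmtPath)
    sel <- selectGenes(expr, gmt, cfg$targetSets, c = cfg$clusters,
                       mFuzz = cfg$mFuzz, fdrCutoff = cfg$fdrCutoff,
                       seed = cfg$seed)
    writeLines(sel$genes, selFile)
    write.table(sel$enrichment, enrFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .stageDone(cfg, "select", selHash)
  }
  selectedGenes <- readLines(selFile, warn = FALSE)
  selectedGenes <- selectedGenes[nzchar(selectedGenes)]
  if (!length(selectedGenes)) {
    .plog(cfg, "[select] no enriched cluster; using all %d genes",
          length(featureIDs(expr)))
    selectedGenes <- featureIDs(expr)
  }
  exprSel <- OmicsBlock(
    blockValues(expr)[, selectedGenes, drop = FALSE], "expression")

  # ---- stage: prioritize-variants / burden
  blocks <- list(expression = exprSel)
  if (!is.null(cfg$variantPath)) {
    burdFile <- file.path(cfg$outDir, "burden.tsv")
    bHash <- .stageHash(c(cfg$variantPath, cfg$samplesPath),
                        list(cfg$scoreMode))
    if (!.stageCached(cfg, "burden", bHash, burdFile)) {
      .plog(cfg, "[burden] filtering and scoring variants")
      recs <- readAnnotatedVariants(cfg$variantPath)
      recs <- filterVariants(recs)
      log <- attr(recs, "filterLog")
      .plog(cfg, "[burden] drops: canonical=%d symbol=%d frequency=%d",
            log["canonical"], log["symbol"], log["frequency"])
      burden <- buildGeneBurden(recs, samples$sample,
                                mode = cfg$scoreMode)
      writeOmicsBlock(burden, burdFile)
      .stageDone(cfg, "burden", bHash)
    }
    blocks$burden <- readExpressionMatrix(burdFile,
                                          orientation = "samples_in_rows",
                                          blockName = "burden")
  } else if (!is.null(cfg$burdenPath)) {
    blocks$burden <- readExpressionMatrix(cfg$burdenPath,
                                          orientation = "samples_in_rows",
                                          blockName = "burden")
  }

  # ---- stage: train + evaluate (cross-validated)
  al <- alignSamples(blocks, samples)
  .plog(cfg, "[evaluate] %d-fold CV on %d samples, %d + %d features",
        cfg$folds, nrow(al$sampleTable),
        length(featureIDs(al$blocks[[1]])),
        if (length(al$blocks) > 1) length(featureIDs(al$blocks[[2]]))
        else 0L)
  trainCfg <- cfg$train
  trainCfg$seed <- cfg$seed
  cv <- crossValidate(al$blocks, al$sampleTable, trainCfg,
                      k = cfg$folds, seed = cfg$seed)
  write.table(cv$perFold, file.path(cfg$outDir, "fold_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cv$pooled, file.path(cfg$outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  # final model on all samples (the deployable checkpoint)
  fit <- trainMoals(al$blocks, al$sampleTable, trainCfg)
  saveRDS(fit, file.path(cfg$outDir, "model.rds"))
  saveRDS(cfg, file.path(cfg$outDir, "config.rds"))
  list(selectedGenes = selectedGenes, evaluation = cv,
       metrics = cv$pooled, outDir = cfg$outDir)
}
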