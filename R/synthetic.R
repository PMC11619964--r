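# Synthetic multi-omics cohort generator.
#
# Emulates the statistical structure the model assumes: a small set of
# latent factors drives (i) block-correlated log-normal expression,
# (ii) sparse Poisson rare-variant burdens with case-enriched signal genes,
# (iii) an imbalanced logistic class label, (iv) a linear-plus-noise onset
# age, and (v) exponential survival with independent uniform censoring
# calibrated to a target censoring fraction.

#' Simulation configuration for a synthetic cohort
#'
#' Defaults emulate a cohort of 672 samples with a 593/79 case/control
#' imbalance. The first latent factor drives the class label and the
#' survival hazard (so classification accuracy and C-index share a common,
#' tunable ceiling); the second drives onset age. Expression genes are
#' split into co-expression blocks, block b loading on latent factor
#' ((b-1) mod latentDimTrue) + 1.
#'
#' @param nSamples total samples.
#' @param nCases,nControls class counts; must sum to \code{nSamples}.
#' @param nGenesExpression,nGenesBurden feature counts per block.
#' @param latentDimTrue number of true latent factors.
#' @param nBlocks number of co-expression blocks.
#' @param blockEffectSize loading magnitude of a gene on its block factor
#'   (0 switches expression signal off).
#' @param noiseSd Gaussian noise sd on the log-expression scale.
#' @param burdenBaseRate per-gene Poisson rate of burden counts.
#' @param burdenSignalRate rate multiplier on signal genes in cases
#'   (1 = no burden signal).
#' @param nSignalGenes number of case-linked burden genes.
#' @param labelLogitScale logistic scale tying the label to latent factor 1.
#' @param onsetIntercept,onsetSlope,onsetNoiseSd onset age model (years):
#'   intercept + slope x latent factor 2 + Gaussian noise.
#' @param hazardBaseline baseline exponential hazard (per time unit; the
#'   default 1/900 gives a median survival around 600 days at the
#'   baseline).
#' @param hazardLogRatio log-hazard increment per unit of latent factor 1.
#' @param censoringFractionTarget target fraction of censored subjects in
#'   [0, 1); censoring times are uniform and independent of covariates.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a validated list of class \code{moalsSimConfig}.
#' @export
simulationConfig <- function(nSamples = 672L, nCases = 593L,
                             nControls = 79L, nGenesExpression = 500L,
                             nGenesBurden = 100L, latentDimTrue = 4L,
                             nBlocks = 4L, blockEffectSize = 1,
                             noiseSd = 0.5, burdenBaseRate = 0.05,
                             burdenSignalRate = 3, nSignalGenes = 50L,
                             labelLogitScale = 4, onsetIntercept = 58,
                             onsetSlope = 6, onsetNoiseSd = 4,
                             hazardBaseline = 1 / 900,
                             hazardLogRatio = 1.2,
                             censoringFractionTarget = 0.3, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), nCases = as.integer(nCases),
              nControls = as.integer(nControls),
              nGenesExpression = as.integer(nGenesExpression),
              nGenesBurden = as.integer(nGenesBurden),
              latentDimTrue = as.integer(latentDimTrue),
              nBlocks = as.integer(nBlocks),
              blockEffectSize = blockEffectSize, noiseSd = noiseSd,
              burdenBaseRate = burdenBaseRate,
              burdenSignalRate = burdenSignalRate,
              nSignalGenes = as.integer(nSignalGenes),
              labelLogitScale = labelLogitScale,
              onsetIntercept = onsetIntercept, onsetSlope = onsetSlope,
              onsetNoiseSd = onsetNoiseSd, hazardBaseline = hazardBaseline,
              hazardLogRatio = hazardLogRatio,
              censoringFractionTarget = censoringFractionTarget,
              seed = as.integer(seed))
  counts <- c(cfg$nSamples, cfg$nGenesExpression, cfg$nGenesBurden,
              cfg$latentDimTrue, cfg$nBlocks)
  if (any(counts <= 0L)) stop("all counts must be positive")
  if (cfg$nCases + cfg$nControls != cfg$nSamples)
    stop(sprintf("nCases (%d) + nControls (%d) != nSamples (%d)",
                 cfg$nCases, cfg$nControls, cfg$nSamples))
  if (cfg$censoringFractionTarget < 0 || cfg$censoringFractionTarget >= 1)
    stop("censoringFractionTarget must lie in [0, 1)")
  if (cfg$burdenBaseRate <= 0 || cfg$burdenSignalRate <= 0 ||
      cfg$hazardBaseline <= 0)
    stop("rates must be positive")
  if (cfg$nSignalGenes > cfg$nGenesBurden)
    stop("nSignalGenes cannot exceed nGenesBurden")
  class(cfg) <- "moalsSimConfig"
  cfg
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws latent factors Z ~ N(0, I), builds expression as
#' \code{exp(Z Lambda' + noise)} with genes grouped into co-expression
#' blocks sharing a latent driver, Poisson burden counts with
#' case-enriched rates on the planted signal genes, a class label from a
#' logistic model on latent factor 1 conditioned on the exact requested
#' case/control split (cases are the \code{nCases} largest values of
#' \code{labelLogitScale x Z1 + logistic noise}), onset age as a linear
#' function of latent factor 2 plus noise, and exponential survival with
#' log-hazard \code{log(hazardBaseline) + hazardLogRatio x Z1}, censored
#' by an independent uniform time calibrated on the drawn event times so
#' the empirical censoring fraction approaches the target.
#'
#' @param config a [simulationConfig()].
#' @return A [SyntheticCohort-class]; bitwise-reproducible from
#'   \code{config$seed}.
#' @examples
#' cfg <- simulationConfig(nSamples = 60, nCases = 45, nControls = 15,
#'                         nGenesExpression = 40, nGenesBurden = 10,
#'                         nSignalGenes = 5)
#' cohort <- generateCohort(cfg)
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "moalsSimConfig"))
  cfg <- config
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv()))

  n <- cfg$nSamples
  ids <- sprintf("S%04d", seq_len(n))
  L <- cfg$latentDimTrue
  Z <- matrix(rnorm(n * L), n, L,
              dimnames = list(ids, paste0("latent", seq_len(L))))

  # expression: blocks of genes sharing a latent driver
  gE <- cfg$nGenesExpression
  exprGenes <- sprintf("EXPR%04d", seq_len(gE))
  blockOf <- sort(rep(seq_len(cfg$nBlocks), length.out = gE))
  names(blockOf) <- exprGenes
  factorOf <- ((blockOf - 1L) %% L) + 1L
  loadings <- cfg$blockEffectSize * runif(gE, 0.5, 1.5)
  logExpr <- Z[, factorOf, drop = FALSE] *
    matrix(loadings, n, gE, byrow = TRUE) +
    matrix(rnorm(n * gE, sd = cfg$noiseSd), n, gE)
  expr <- exp(logExpr)
  dimnames(expr) <- list(ids, exprGenes)

  # class label: logistic model on Z1, conditioned on the exact split
  logit <- cfg$labelLogitScale * Z[, 1]
  u <- logit + rlogis(n)
  caseIdx <- order(u, decreasing = TRUE)[seq_len(cfg$nCases)]
  label <- factor(ifelse(seq_len(n) %in% caseIdx, "case", "control"),
                  levels = c("control", "case"))

  # burden: Poisson counts, case-linked rate on signal genes
  gB <- cfg$nGenesBurden
  burdenGenes <- sprintf("BURD%04d", seq_len(gB))
  signalGenes <- burdenGenes[seq_len(cfg$nSignalGenes)]
  rates <- matrix(cfg$burdenBaseRate, n, gB, dimnames = list(ids, burdenGenes))
  rates[label == "case", signalGenes] <-
    cfg$burdenBaseRate * cfg$burdenSignalRate
  burden <- matrix(rpois(n * gB, rates), n, gB,
                   dimnames = list(ids, burdenGenes))

  # onset age: linear in Z2 plus noise
  onset <- cfg$onsetIntercept + cfg$onsetSlope * Z[, min(2L, L)] +
    rnorm(n, sd = cfg$onsetNoiseSd)

  # survival: exponential with log-hazard linear in Z1, uniform censoring
  eta <- cfg$hazardLogRatio * Z[, 1]
  eventTime <- rexp(n, rate = cfg$hazardBaseline * exp(eta))
  if (cfg$censoringFractionTarget > 0) {
    # calibrate Unif(0, cmax): P(censor | T) = min(T, cmax) / cmax
    f <- function(cmax) mean(pmin(eventTime, cmax) / cmax) -
      cfg$censoringFractionTarget
    upper <- max(eventTime) * 2
    cmax <- if (f(upper) > 0) upper else
      uniroot(f, c(min(eventTime) / 2, upper))$root
    censTime <- runif(n, 0, cmax)
  } else censTime <- rep(Inf, n)
  time <- pmin(eventTime, censTime)
  event <- as.integer(eventTime <= censTime)

  samples <- data.frame(sample = ids, label = label, onset_age = onset,
                        time = time, event = event,
                        stringsAsFactors = FALSE)
  new("SyntheticCohort",
      expression = OmicsBlock(expr, "expression"),
      burden = OmicsBlock(burden, "burden"),
      samples = samples, latent = Z, geneBlocks = blockOf,
      signalGenes = signalGenes, risk = setNames(eta, ids),
      config = unclass(cfg))
}

#' Ground-truth report of the planted structure
#'
#' Emits the planted gene-block assignments of expression genes and the
#' case-linked burden signal genes, for parameter-recovery tests. The
#' report depends only on the planted truth, so it is invariant to the
#' order of samples in the cohort.
#'
#' @param cohort a [SyntheticCohort-class].
#' @return data.frame with columns \code{gene}, \code{omics}
#'   (\code{"expression"} or \code{"burden"}), \code{block}
#'   (co-expression block index; NA for burden genes), \code{signal}
#'   (logical: case-linked burden gene).
#' @export
plantedTruthReport <- function(cohort) {
  stopifnot(is(cohort, "SyntheticCohort"))
  exprGenes <- names(cohort@geneBlocks)
  burdenGenes <- featureIDs(cohort@burden)
  rbind(
    data.frame(gene = exprGenes, omics = "expression",
               block = as.integer(cohort@geneBlocks),
               signal = FALSE, stringsAsFactors = FALSE),
    data.frame(gene = burdenGenes, omics = "burden", block = NA_integer_,
               signal = burdenGenes %in% cohort@signalGenes,
               stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to a directory
#'
#' Emits \code{expression.tsv} (genes in rows, the conventional
#' expression-matrix layout, ready for [readExpressionMatrix()] and the
#' pipeline), \code{burden.tsv} (samples in rows), \code{samples.tsv}
#' and \code{truth.tsv} (the [plantedTruthReport()]).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- t(blockValues(cohort@expression))
  df <- data.frame(gene = rownames(ev), check.names = FALSE)
  df[colnames(ev)] <- as.data.frame(format(ev, digits = 15, trim = TRUE,
                                           scientific = FALSE))
  write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeOmicsBlock(cohort@burden, file.path(dir, "burden.tsv"))
  writeSampleTable(cohort@samples, file.path(dir, "samples.tsv"))
  write.table(plantedTruthReport(cohort), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
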