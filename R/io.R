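# Readers/writers for the delimited formats the pipeline touches.
# All readers validate eagerly so downstream math never sees malformed data.

.moalsFormatError <- function(fmt, ...) {
  stop(structure(class = c("moalsFormatError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path)) .moalsFormatError("file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) .moalsFormatError("cannot parse %s: %s", path,
                                          conditionMessage(e)))
  df
}

#' Read a gene-expression matrix
#'
#' Reads a delimited text file (TSV or CSV, by extension) with one header
#' row and one leading identifier column, and returns an expression
#' [OmicsBlock-class] in samples x features orientation. Negative,
#' non-numeric, or missing cells and duplicated identifiers are rejected.
#'
#' @param path file path.
#' @param orientation \code{"genes_in_rows"} (the common export layout;
#'   the matrix is transposed on load) or \code{"samples_in_rows"}.
#' @param blockName label for the returned block.
#' @return An [OmicsBlock-class], samples x features.
#' @seealso [writeOmicsBlock()] for the inverse operation.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows"),
                                 blockName = "expression") {
  orientation <- match.arg(orientation)
  df <- .readDelim(path)
  if (ncol(df) < 2L)
    .moalsFormatError("expression matrix needs an id column plus data: %s",
                      path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    .moalsFormatError("duplicate identifiers in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m))
    .moalsFormatError("non-numeric or missing cells in %s", path)
  if (any(m < 0))
    .moalsFormatError("negative expression values in %s", path)
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)
  if (anyDuplicated(rownames(m)))
    .moalsFormatError("duplicate sample identifiers in %s", path)
  OmicsBlock(m, blockName = blockName)
}

#' Write an OmicsBlock to TSV
#'
#' Emits a TSV with samples in rows (a leading \code{sample} column) and one
#' column per feature; [readExpressionMatrix()] with
#' \code{orientation = "samples_in_rows"} restores it exactly (within
#' the printed precision, 15 significant digits).
#'
#' @param block an [OmicsBlock-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOmicsBlock <- function(block, path) {
  stopifnot(is(block, "OmicsBlock"))
  v <- blockValues(block)
  df <- data.frame(sample = rownames(v), check.names = FALSE)
  df[colnames(v)] <- as.data.frame(format(v, digits = 15, trim = TRUE,
                                          scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a set are collapsed; a duplicated set name or a line with fewer
#' than three fields is a format error.
#'
#' @param path GMT file path.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) .moalsFormatError("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      .moalsFormatError("GMT line %d has fewer than 3 fields", i)
    nm <- f[1]
    if (nm %in% names(sets))
      .moalsFormatError("gene set '%s' listed twice (line %d)", nm, i)
    sets[[nm]] <- unique(f[-(1:2)])
    descs[nm] <- f[2]
  }
  GeneSetCollection(sets, descs)
}

#' Write a GeneSetCollection to GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(gsc, path) {
  stopifnot(is(gsc, "GeneSetCollection"))
  lines <- vapply(names(gsc@sets), function(nm) {
    paste(c(nm, gsc@descriptions[[nm]], gsc@sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Loads the cohort metadata used by the supervised heads: class label,
#' onset age (years; may be missing), survival time (non-negative), and
#' event indicator (1 = event observed, 0 = censored). Column names are
#' declared by the caller so arbitrary exports can be consumed.
#'
#' @param path delimited text file (TSV or CSV by extension).
#' @param sampleCol,labelCol,onsetCol,timeCol,eventCol column names in the
#'   file. \code{onsetCol}, \code{timeCol}, \code{eventCol} may be `NA` to
#'   mark the field as unavailable.
#' @return A data.frame with canonical columns \code{sample}, \code{label}
#'   (factor), \code{onset_age}, \code{time}, \code{event}.
#' @export
readSampleTable <- function(path, sampleCol = "sample", labelCol = "label",
                            onsetCol = "onset_age", timeCol = "time",
                            eventCol = "event") {
  df <- .readDelim(path)
  need <- c(sampleCol, labelCol)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .moalsFormatError("missing column(s) in %s: %s", path,
                      paste(miss, collapse = ", "))
  out <- data.frame(sample = as.character(df[[sampleCol]]),
                    label = factor(df[[labelCol]]),
                    stringsAsFactors = FALSE)
  pull <- function(col) {
    if (is.na(col) || !col %in% colnames(df)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(df[[col]]))
  }
  out$onset_age <- pull(onsetCol)
  out$time <- pull(timeCol)
  out$event <- pull(eventCol)
  validateSampleTable(out)
  out
}

#' Validate a sample table
#'
#' Checks the invariants of the cohort metadata contract: unique sample
#' ids, event indicator in \{0, 1\}, non-negative survival times.
#'
#' @param tab data.frame with columns \code{sample}, \code{label}, and
#'   optionally \code{onset_age}, \code{time}, \code{event}.
#' @return \code{tab} invisibly; errors on violation.
#' @export
validateSampleTable <- function(tab) {
  if (anyDuplicated(tab$sample))
    .moalsFormatError("duplicate sample identifiers: %s",
      paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  ev <- tab$event[!is.na(tab$event)]
  if (length(ev) && !all(ev %in% c(0, 1)))
    .moalsFormatError("event indicator outside {0,1}: %s",
      paste(unique(ev[!ev %in% c(0, 1)]), collapse = ", "))
  tt <- tab$time[!is.na(tab$time)]
  if (length(tt) && any(tt < 0))
    .moalsFormatError("negative survival times present")
  invisible(tab)
}

#' Write a sample table to TSV
#'
#' @param tab sample table data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omics blocks and a sample table to one shared sample order
#'
#' Reindexes every block to the sample order of the table, keeping only
#' samples present everywhere, and asserts the resulting identifier lists
#' are identical. Downstream training assumes this alignment.
#'
#' @param blocks named list of [OmicsBlock-class] objects.
#' @param sampleTable sample metadata data.frame with a \code{sample} column.
#' @return list with elements \code{blocks} (reordered) and
#'   \code{sampleTable} (subset, same order).
#' @export
alignSamples <- function(blocks, sampleTable) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  shared <- sampleTable$sample
  for (b in blocks) shared <- intersect(shared, sampleIDs(b))
  if (!length(shared))
    .moalsFormatError("no samples shared across blocks and sample table")
  sampleTable <- sampleTable[match(shared, sampleTable$sample), , drop = FALSE]
  rownames(sampleTable) <- NULL
  blocks <- lapply(blocks, function(b)
    OmicsBlock(blockValues(b)[shared, , drop = FALSE], blockName(b)))
  for (b in blocks)
    stopifnot(identical(sampleIDs(b), sampleTable$sample))
  list(blocks = blocks, sampleTable = sampleTable)
}
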