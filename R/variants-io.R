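# Reader for VEP-style annotated variants, from VCF (INFO/CSQ) or from a
# flat TSV dialect. Records come back as a data.frame with one row per
# variant-consequence-sample combination carrying a non-reference genotype.

.csqRequired <- c("Consequence", "SYMBOL", "CANONICAL")
.csqAfFields <- c("AF", "MAX_AF", "gnomAD_AF", "gnomADe_AF", "ExAC_AF")

.emptyVariantFrame <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), consequence = character(),
             canonical = logical(), af = numeric(), sample = character(),
             count = integer(), stringsAsFactors = FALSE)
}

.gtToCount <- function(gt) {
  # count of non-reference alleles in a diploid GT string; "." -> 0
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(0L)
  alleles <- strsplit(gt, "[/|]")[[1]]
  sum(alleles != "0" & alleles != ".")
}

#' Read VEP-annotated variants
#'
#' Parses a VCF with per-ALT CSQ annotation (fields \code{Consequence},
#' \code{SYMBOL}, \code{CANONICAL} and a population allele-frequency field
#' such as \code{AF} or \code{gnomAD_AF} must be declared in the CSQ format
#' string), or an equivalent flat TSV (columns \code{sample}, \code{gene},
#' \code{consequence}, \code{af}, \code{canonical}, \code{count}; column
#' names overridable via \code{columns}).
#'
#' One record is returned per variant x consequence-annotation x sample
#' combination where the sample carries at least one non-reference allele.
#' A missing allele frequency (empty CSQ subfield) is preserved as `NA`,
#' meaning "absent from large population panels" — it is deliberately not
#' imputed to 0, because such variants pass the rarity filter.
#'
#' @param path VCF (\code{.vcf}) or delimited text file.
#' @param format \code{"auto"} (by extension), \code{"vcf"}, or \code{"tsv"}.
#' @param columns named character vector mapping the canonical flat-TSV
#'   column roles (\code{sample}, \code{gene}, \code{consequence},
#'   \code{af}, \code{canonical}, \code{count}) to file column names.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene}, \code{consequence} (\code{&}-separated terms),
#'   \code{canonical}, \code{af}, \code{sample}, \code{count}.
#' @seealso [filterVariants()], [buildGeneBurden()].
#' @export
readAnnotatedVariants <- function(path, format = c("auto", "vcf", "tsv"),
                                  columns = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .readVariantsVcf(path) else
    .readVariantsTsv(path, columns)
}

.readVariantsVcf <- function(path) {
  if (!file.exists(path)) .moalsFormatError("file not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::info(VariantAnnotation::header(vcf))
  if (!"CSQ" %in% rownames(hdr))
    .moalsFormatError("VCF %s has no INFO/CSQ annotation", path)
  desc <- hdr["CSQ", "Description"]
  fmt <- sub(".*Format:\\s*", "", desc)
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  miss <- setdiff(.csqRequired, fields)
  if (length(miss))
    .moalsFormatError("CSQ annotation lacks mandatory subfield(s): %s",
                      paste(miss, collapse = ", "))
  afField <- intersect(.csqAfFields, fields)[1]
  if (is.na(afField))
    .moalsFormatError(
      "CSQ annotation lacks a population allele-frequency subfield (one of %s)",
      paste(.csqAfFields, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    .moalsFormatError("VCF %s has no GT genotypes", path)
  csq <- VariantAnnotation::info(vcf)$CSQ
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  refs <- as.character(rr$REF)
  alts <- vapply(rr$ALT, function(a) as.character(a)[1], character(1))
  samples <- colnames(gt)

  out <- vector("list", length(rr))
  for (i in seq_along(rr)) {
    anns <- csq[[i]]
    counts <- vapply(gt[i, , drop = TRUE], .gtToCount, integer(1))
    carriers <- samples[counts > 0]
    if (!length(anns) || !length(carriers)) next
    rows <- vector("list", length(anns))
    for (a in seq_along(anns)) {
      vals <- strsplit(anns[[a]], "|", fixed = TRUE)[[1]]
      length(vals) <- length(fields)  # pad dropped trailing empties
      names(vals) <- fields
      afRaw <- vals[[afField]]
      af <- if (is.na(afRaw) || !nzchar(afRaw)) NA_real_ else
        suppressWarnings(as.numeric(afRaw))
      gene <- vals[["SYMBOL"]]
      rows[[a]] <- data.frame(
        chrom = chroms[i], pos = poss[i], ref = refs[i], alt = alts[i],
        gene = if (is.na(gene) || !nzchar(gene)) NA_character_ else gene,
        consequence = vals[["Consequence"]],
        canonical = identical(toupper(vals[["CANONICAL"]]), "YES"),
        af = af, sample = carriers,
        count = counts[carriers], stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else .emptyVariantFrame()
  rownames(res) <- NULL
  res
}

.readVariantsTsv <- function(path, columns = NULL) {
  cols <- c(sample = "sample", gene = "gene", consequence = "consequence",
            af = "af", canonical = "canonical", count = "count")
  if (!is.null(columns)) cols[names(columns)] <- columns
  df <- .readDelim(path)
  miss <- setdiff(unname(cols), colnames(df))
  if (length(miss))
    .moalsFormatError("variant table %s lacks column(s): %s", path,
                      paste(miss, collapse = ", "))
  canon <- df[[cols[["canonical"]]]]
  canon <- toupper(as.character(canon)) %in% c("YES", "TRUE", "1")
  af <- suppressWarnings(as.numeric(df[[cols[["af"]]]]))
  gene <- as.character(df[[cols[["gene"]]]])
  gene[!nzchar(gene) | gene == "NA"] <- NA_character_
  res <- data.frame(
    chrom = if ("chrom" %in% colnames(df)) as.character(df$chrom)
            else NA_character_,
    pos = if ("pos" %in% colnames(df)) as.integer(df$pos) else NA_integer_,
    ref = if ("ref" %in% colnames(df)) as.character(df$ref)
          else NA_character_,
    alt = if ("alt" %in% colnames(df)) as.character(df$alt)
          else NA_character_,
    gene = gene,
    consequence = as.character(df[[cols[["consequence"]]]]),
    canonical = canon, af = af,
    sample = as.character(df[[cols[["sample"]]]]),
    count = as.integer(df[[cols[["count"]]]]), stringsAsFactors = FALSE)
  bad <- res$af[!is.na(res$af)]
  if (length(bad) && any(bad < 0 | bad > 1))
    .moalsFormatError("allele frequencies outside [0,1] in %s", path)
  if (any(!res$count %in% 0:2))
    .moalsFormatError("allele counts outside {0,1,2} in %s", path)
  res
}
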