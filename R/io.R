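#' Read a genome FASTA into a DNAStringSet
#'
#' Loads every FASTA record as one chromosome. Lowercase bases are
#' uppercased and IUPAC ambiguity codes are mapped to \code{N}; a warning
#' reports how many characters were remapped. Bases outside the FASTA
#' alphabet make \code{\link[Biostrings]{readDNAStringSet}} fail, which is
#' the intended strictness.
#'
#' @param path path to a (plain or gzipped) FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} over \{A,C,G,T,N\},
#'   named by chromosome. The number of remapped characters is attached as
#'   attribute \code{"n_ambiguous"} via \code{metadata}-style attribute.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0L) stop("empty FASTA: ", path)
  if (anyDuplicated(names(genome)))
    stop("duplicate record names in FASTA: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  if (any(Biostrings::width(genome) == 0L))
    stop("FASTA contains an empty record")
  freq <- Biostrings::alphabetFrequency(genome)
  nAmb <- sum(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"), drop = FALSE])
  if (nAmb > 0) {
    warning(nAmb, " non-ACGTN character(s) mapped to N")
    genome <- Biostrings::replaceAmbiguities(genome, new = "N")
  }
  attr(genome, "n_ambiguous") <- nAmb
  genome
}

.ROLES <- c("proband", "sibling")
.SEXES <- c("male", "female")

#' Read a de novo variant table
#'
#' Tab-separated with a header naming at least \code{chrom}, \code{pos},
#' \code{family_id}, \code{role} and \code{sex}. Optional columns:
#' \code{variant_id} (synthesized from chrom/pos/family/role when absent),
#' \code{score} (e.g. an externally supplied disease impact score) and any
#' number of \code{lane_*} columns carrying sequencing-lane metadata.
#'
#' @param path path to the TSV file.
#' @return a data.frame of variant records; positions are 1-based integers.
#' @export
readVariantTable <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, quote = "")
  required <- c("chrom", "pos", "family_id", "role", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("variant table lacks required column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), family_id = character(),
                      role = character(), sex = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos != round(pos))
  if (length(bad))
    stop("non-integer pos in variant table row(s): ", paste(bad, collapse = ", "))
  if (any(pos < 1)) stop("pos must be >= 1")
  badRole <- which(!df$role %in% .ROLES)
  if (length(badRole))
    stop("unknown role '", df$role[badRole[1L]], "' in row ", badRole[1L])
  badSex <- which(!df$sex %in% .SEXES)
  if (length(badSex))
    stop("unknown sex '", df$sex[badSex[1L]], "' in row ", badSex[1L])
  out <- data.frame(
    variant_id = if ("variant_id" %in% names(df)) df$variant_id else
      paste(df$chrom, as.integer(pos), df$family_id, df$role, sep = ":"),
    chrom = df$chrom, pos = as.integer(pos),
    family_id = df$family_id, role = df$role, sex = df$sex,
    stringsAsFactors = FALSE)
  if ("score" %in% names(df)) out$score <- as.numeric(df$score)
  laneCols <- grep("^lane_", names(df), value = TRUE)
  for (lc in laneCols) out[[lc]] <- df[[lc]]
  key <- paste(out$chrom, out$pos, out$family_id, out$role)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos, family_id, role) in variant table")
  out
}

#' Write a variant (or any) table as TSV
#'
#' Floating point columns are written with 6 significant digits; all other
#' columns as-is. Used for every tabular output of the pipeline.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
writeTsv <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- signif(fmt[[j]], 6L)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
writeVariantTable <- function(df, path) writeTsv(df, path)

#' Read a square gene-gene correlation matrix
#'
#' Tab-separated square numeric matrix with matching row and column gene-id
#' headers (Geneshot-style export). Symmetry is validated to 1e-8; gene
#' order is preserved.
#'
#' @param path path to the TSV matrix.
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
readCorrelationMatrix <- function(path) {
  if (!file.exists(path)) stop("correlation matrix not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, quote = "")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("correlation matrix is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column gene ids of the correlation matrix do not match")
  storage.mode(m) <- "double"
  methods::new("CorrelationMatrix", correlations = m)
}

#' Construct a CorrelationMatrix from an in-memory matrix
#'
#' @param m square symmetric numeric matrix with identical row/column names.
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
CorrelationMatrix <- function(m) methods::new("CorrelationMatrix", correlations = m)

#' Genes ordered by closeness to a center gene
#'
#' Visiting order used for neighborhood construction: the center gene
#' first, then the remaining genes by descending correlation to the center,
#' correlation ties broken by ascending gene id (a deterministic rendering
#' of "ties broken arbitrarily").
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param gene center gene id.
#' @return character vector of gene ids, center first.
#' @export
closestGenes <- function(corr, gene) {
  ids <- geneIds(corr)
  if (!gene %in% ids) stop("gene not present in correlation matrix: ", gene)
  row <- corr@correlations[gene, ]
  others <- setdiff(ids, gene)
  ord <- others[order(-row[others], others)]
  c(gene, ord)
}

#' Read BED interval annotations
#'
#' BED3 (or BED4 when \code{labeled = TRUE}) with 0-based half-open
#' coordinates; returned as a sorted \code{\link[GenomicRanges]{GRanges}}
#' in 1-based closed convention (BED line \code{chr1 0 10} covers 1-based
#' positions 1..10). Overlapping intervals with the same label are
#' permitted.
#'
#' @param path path to the BED file.
#' @param labeled when TRUE, column 4 is attached as metadata column
#'   \code{label} (e.g. a chromatin-state mnemonic).
#' @return a sorted \code{GRanges}.
#' @export
readIntervalAnnotations <- function(path, labeled = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (ncol(df) < 3L) stop("BED needs at least 3 columns")
  if (labeled && ncol(df) < 4L) stop("labeled BED needs 4 columns")
  start <- suppressWarnings(as.numeric(df[[2L]]))
  end <- suppressWarnings(as.numeric(df[[3L]]))
  if (any(is.na(start) | is.na(end) | start != round(start) | end != round(end)))
    stop("non-integer coordinates in BED")
  if (any(start >= end))
    stop("BED interval with start >= end at line ", which(start >= end)[1L])
  gr <- GenomicRanges::GRanges(df[[1L]],
                               IRanges::IRanges(start = start + 1L, end = end))
  if (labeled) gr$label <- df[[4L]]
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read a gene TSS table
#'
#' Tab-separated with header columns \code{gene_id}, \code{chrom},
#' \code{strand} and \code{tss} (1-based coordinate of the outermost TSS:
#' the 5'-most position of the gene in transcription orientation).
#'
#' @param path path to the TSV file.
#' @return a data.frame with one row per gene.
#' @export
readTssTable <- function(path) {
  if (!file.exists(path)) stop("TSS table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("gene_id", "chrom", "strand", "tss")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("TSS table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in TSS table")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- suppressWarnings(as.numeric(df$tss))
  if (any(is.na(tss) | tss != round(tss) | tss < 1)) stop("tss must be a positive integer")
  df$tss <- as.integer(tss)
  df[, required]
}

#' Thin VCF position adapter
#'
#' Reads only chromosome and 1-based position from a plain-text VCF, for
#' callers whose variants arrive as VCF instead of the canonical flat TSV.
#' Family/role/sex metadata must be supplied separately. No INFO parsing.
#'
#' @param path path to an uncompressed VCF file.
#' @return data.frame with columns \code{chrom}, \code{pos}.
#' @export
readVcfPositions <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L)
    return(data.frame(chrom = character(), pos = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos)) stop("non-integer POS in VCF")
  data.frame(chrom = vapply(parts, `[[`, "", 1L), pos = pos,
             stringsAsFactors = FALSE)
}
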