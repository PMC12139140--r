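#' Extract the L-bp window centered on a position
#'
#' @param genome a \code{DNAStringSet} from [readGenomeFasta()].
#' @param chrom chromosome name.
#' @param pos 1-based variant position.
#' @param L odd window length (default 201: 100 bp of flank on each side).
#' @return the window as an uppercase character string.
#' @export
extractWindow <- function(genome, chrom, pos, L = 201L) {
  if (L %% 2L != 1L) stop("L must be odd")
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  flank <- (L - 1L) %/% 2L
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (pos - flank < 1L || pos + flank > len)
    stop("window off chromosome end for ", chrom, ":", pos)
  as.character(Biostrings::subseq(genome[[chrom]], pos - flank, pos + flank))
}

#' Vectorized window extraction
#'
#' Extracts windows for many variants at once; variants whose window would
#' run off a chromosome end are dropped with a warning reporting the count
#' (they cannot be length-L and are excluded rather than padded).
#'
#' @param genome a \code{DNAStringSet}.
#' @param variants data.frame with \code{chrom} and \code{pos}.
#' @inheritParams extractWindow
#' @return list with \code{windows} (a \code{DNAStringSet}, one entry per
#'   retained variant), \code{keep} (logical index into \code{variants})
#'   and \code{n_dropped}.
#' @export
extractWindows <- function(genome, variants, L = 201L) {
  if (L %% 2L != 1L) stop("L must be odd")
  flank <- (L - 1L) %/% 2L
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (!all(variants$chrom %in% names(genome)))
    stop("variant on chromosome absent from genome")
  keep <- variants$pos - flank >= 1L & variants$pos + flank <= lens[variants$chrom]
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    warning(nDropped, " variant(s) dropped: window off chromosome end")
  v <- variants[keep, , drop = FALSE]
  windows <- Biostrings::subseq(genome[v$chrom], start = v$pos - flank, width = L)
  if (length(windows)) names(windows) <- v$variant_id
  list(windows = windows, keep = keep, n_dropped = nDropped)
}

#' Local GC content of windows
#'
#' Counts G or C bases; N counts as non-GC.
#'
#' @param windows a \code{DNAStringSet} or character vector of windows.
#' @return integer vector of GC counts.
#' @export
localGcContent <- function(windows) {
  if (is.character(windows)) windows <- Biostrings::DNAStringSet(windows)
  if (any(Biostrings::width(windows) == 0L)) stop("empty window")
  as.integer(Biostrings::letterFrequency(windows, letters = "GC"))
}

#' Overlapping k-mer counts of windows
#'
#' Counts the |window| - k + 1 overlapping k-mers of each window over the
#' 4^k k-mers in lexicographic order; any k-mer containing a non-ACGT
#' character is skipped (counted nowhere).
#'
#' @param windows a \code{DNAStringSet} or character vector.
#' @param k k-mer length in 1..7.
#' @return integer matrix, one row per window, 4^k lexicographic columns.
#' @export
kmerCounts <- function(windows, k) {
  if (k < 1L || k > 7L) stop("k must be in 1..7")
  if (is.character(windows)) windows <- Biostrings::DNAStringSet(windows)
  if (any(Biostrings::width(windows) < k)) stop("window shorter than k")
  Biostrings::oligonucleotideFrequency(windows, width = k)
}

#' Assign variants to their nearest outermost TSS
#'
#' Each variant is assigned to the gene whose outermost TSS minimizes the
#' absolute genomic distance; variants farther than \code{maxDist} from
#' every TSS remain unassigned. The stored \code{tss_distance} is signed in
#' gene orientation: negative means upstream of the TSS (5' of it in the
#' gene's direction of transcription). Equidistant ties go to the
#' lexicographically smaller gene id.
#'
#' @param variants data.frame with \code{chrom} and \code{pos}.
#' @param tssTable data.frame from [readTssTable()].
#' @param maxDist assignment radius in bp (default 100000).
#' @return \code{variants} with columns \code{gene_id}, \code{tss_distance}
#'   and \code{orientation} (\code{upstream}/\code{downstream}/
#'   \code{unassigned}) appended.
#' @export
assignToTss <- function(variants, tssTable, maxDist = 100000L) {
  if (nrow(tssTable) == 0L) stop("empty TSS table")
  n <- nrow(variants)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  for (chr in unique(variants$chrom)) {
    vi <- which(variants$chrom == chr)
    tt <- tssTable[tssTable$chrom == chr, , drop = FALSE]
    if (nrow(tt) == 0L) next
    # order TSSs by (coordinate, gene_id) so ties resolve to the smaller id
    tt <- tt[order(tt$tss, tt$gene_id), , drop = FALSE]
    pos <- variants$pos[vi]
    idx <- findInterval(pos, tt$tss)
    for (j in seq_along(vi)) {
      cand <- unique(pmin(pmax(c(idx[j], idx[j] + 1L), 1L), nrow(tt)))
      d <- abs(pos[j] - tt$tss[cand])
      best <- cand[which.min(d)]  # which.min keeps the first (smaller id) on ties
      if (min(d) <= maxDist) {
        gene[vi[j]] <- tt$gene_id[best]
        signed <- pos[j] - tt$tss[best]
        if (tt$strand[best] == "-") signed <- -signed
        dist[vi[j]] <- signed
      }
    }
  }
  variants$gene_id <- gene
  variants$tss_distance <- dist
  variants$orientation <- ifelse(is.na(gene), "unassigned",
                                 ifelse(dist < 0L, "upstream", "downstream"))
  variants
}

#' Strand-aware upstream/downstream classification
#'
#' A variant is upstream when its coordinate is less than the TSS of its
#' assigned gene on the positive strand, or greater than the TSS on the
#' negative strand; all remaining assigned variants (including a variant
#' exactly at the TSS) are downstream.
#'
#' @param pos 1-based variant position(s).
#' @param tss TSS coordinate(s).
#' @param strand \code{"+"} or \code{"-"} (recycled).
#' @return character vector of \code{"upstream"}/\code{"downstream"}.
#' @export
classifyUpstream <- function(pos, tss, strand) {
  up <- ifelse(strand == "+", pos < tss, pos > tss)
  ifelse(up, "upstream", "downstream")
}

#' Exclusion, orientation, distance and promoter filters
#'
#' Filters are applied in a fixed order with an audit count per filter:
#' (1) variants overlapping any exclusion interval set (coding, canonical
#' splice sites, repeats, ... -- whatever the caller supplies), (2)
#' orientation and TSS-distance restriction, (3) optional promoter
#' exclusion, dropping upstream variants strictly closer than
#' \code{promoterExclusion} bp upstream of their assigned TSS.
#'
#' @param variants annotated variants (after [assignToTss()]).
#' @param exclusions named list of \code{GRanges} interval sets.
#' @param keepOrientation optional \code{"upstream"} or \code{"downstream"};
#'   unassigned variants are dropped whenever a distance or orientation
#'   restriction is in force.
#' @param maxDist keep only variants assigned within this radius (applies
#'   through the assignment; unassigned variants are dropped when not NULL).
#' @param promoterExclusion optional bp; e.g. 2000 drops variants < 2 kbp
#'   upstream of their assigned TSS.
#' @return list with \code{variants} (filtered) and \code{drop_counts}
#'   (named integer vector in application order).
#' @export
filterVariants <- function(variants, exclusions = list(),
                           keepOrientation = NULL, maxDist = NULL,
                           promoterExclusion = NULL) {
  counts <- integer(0)
  if (length(exclusions)) {
    gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
    for (nm in names(exclusions)) {
      hit <- IRanges::overlapsAny(gr, exclusions[[nm]], ignore.strand = TRUE)
      counts[nm] <- sum(hit)
      variants <- variants[!hit, , drop = FALSE]
      gr <- gr[!hit]
    }
  }
  if (!is.null(maxDist)) {
    drop <- is.na(variants$gene_id) | abs(variants$tss_distance) > maxDist
    counts["distance"] <- sum(drop)
    variants <- variants[!drop, , drop = FALSE]
  }
  if (!is.null(keepOrientation)) {
    keepOrientation <- match.arg(keepOrientation, c("upstream", "downstream"))
    drop <- variants$orientation != keepOrientation
    counts["orientation"] <- sum(drop)
    variants <- variants[!drop, , drop = FALSE]
  }
  if (!is.null(promoterExclusion)) {
    drop <- !is.na(variants$gene_id) & variants$tss_distance < 0L &
      -variants$tss_distance < promoterExclusion
    counts["promoter"] <- sum(drop)
    variants <- variants[!drop, , drop = FALSE]
  }
  list(variants = variants, drop_counts = counts)
}

#' Greedy pruning of nearby variants
#'
#' Per chromosome, variants are scanned in ascending coordinate order and a
#' variant is kept iff its distance to the most recently kept variant is at
#' least \code{minGap}. For window length L this guarantees non-overlapping
#' windows when \code{minGap = ceiling(L/2)} (101 for L = 201); of each
#' close pair the smaller coordinate survives.
#'
#' @param variants data.frame with \code{chrom} and \code{pos}.
#' @param minGap minimum allowed |pos difference| between kept variants.
#' @return the pruned data.frame (original row order restored within the
#'   kept set).
#' @export
greedyPrune <- function(variants, minGap = 101L) {
  if (nrow(variants) == 0L) return(variants)
  keep <- logical(nrow(variants))
  for (chr in unique(variants$chrom)) {
    vi <- which(variants$chrom == chr)
    vi <- vi[order(variants$pos[vi])]
    last <- -Inf
    for (i in vi) {
      if (variants$pos[i] - last >= minGap) {
        keep[i] <- TRUE
        last <- variants$pos[i]
      }
    }
  }
  variants[keep, , drop = FALSE]
}

#' Stratify variants by family sex combination and lane matching
#'
#' Keeps variants from families matching the requested proband/sibling sex
#' combination; optionally restricts to families whose proband and sibling
#' have exactly matching (or mismatching) sequencing-lane metadata, where a
#' match means equality of the full tuple of \code{lane_*} column values
#' between the pair members.
#'
#' @param variants variant data.frame with \code{family_id}, \code{role},
#'   \code{sex} and optional \code{lane_*} columns.
#' @param probandSex,siblingSex optional \code{"male"}/\code{"female"}.
#' @param laneMatch optional \code{"match"} or \code{"mismatch"}.
#' @return the stratified subset.
#' @export
stratifyVariants <- function(variants, probandSex = NULL, siblingSex = NULL,
                             laneMatch = NULL) {
  famSex <- function(role) {
    sx <- tapply(variants$sex[variants$role == role],
                 variants$family_id[variants$role == role],
                 function(x) x[1L])
    sx
  }
  keepFam <- unique(variants$family_id)
  if (!is.null(probandSex)) {
    sx <- famSex("proband")
    keepFam <- intersect(keepFam, names(sx)[sx == probandSex])
  }
  if (!is.null(siblingSex)) {
    sx <- famSex("sibling")
    keepFam <- intersect(keepFam, names(sx)[sx == siblingSex])
  }
  if (!is.null(laneMatch)) {
    laneMatch <- match.arg(laneMatch, c("match", "mismatch"))
    laneCols <- grep("^lane_", names(variants), value = TRUE)
    if (length(laneCols) == 0L)
      stop("lane stratification requested but no lane_* columns present")
    tuple <- do.call(paste, c(variants[laneCols], sep = "\r"))
    famTuple <- function(role) {
      idx <- variants$role == role
      tapply(tuple[idx], variants$family_id[idx], function(x) x[1L])
    }
    tp <- famTuple("proband"); ts <- famTuple("sibling")
    common <- intersect(names(tp), names(ts))
    matched <- common[tp[common] == ts[common]]
    wanted <- if (laneMatch == "match") matched else setdiff(common, matched)
    keepFam <- intersect(keepFam, wanted)
  }
  variants[variants$family_id %in% keepFam, , drop = FALSE]
}

#' Prepare variants end to end
#'
#' Convenience wrapper chaining window extraction, local GC content,
#' TSS assignment, filters and greedy pruning -- the "prepare" stage of the
#' pipeline. Returns analysis-ready variants carrying \code{window},
#' \code{gc_count}, \code{gene_id}, \code{tss_distance}, \code{orientation}.
#'
#' @param variants data.frame from [readVariantTable()].
#' @param genome \code{DNAStringSet} from [readGenomeFasta()].
#' @param tssTable data.frame from [readTssTable()].
#' @param exclusions named list of \code{GRanges}.
#' @param L window length (odd; default 201).
#' @param maxDist TSS assignment radius (default 100000).
#' @param keepOrientation optional orientation restriction.
#' @param promoterExclusion optional promoter exclusion radius in bp.
#' @param minGap greedy-pruning gap (default ceiling(L/2)).
#' @return list with \code{variants} (prepared data.frame) and
#'   \code{drop_counts}.
#' @export
prepareVariants <- function(variants, genome, tssTable,
                            exclusions = list(), L = 201L,
                            maxDist = 100000L, keepOrientation = NULL,
                            promoterExclusion = NULL,
                            minGap = as.integer(ceiling(L / 2))) {
  ex <- extractWindows(genome, variants, L = L)
  v <- variants[ex$keep, , drop = FALSE]
  v$window <- as.character(ex$windows)
  v$gc_count <- localGcContent(ex$windows)
  v <- assignToTss(v, tssTable, maxDist = maxDist)
  fl <- filterVariants(v, exclusions = exclusions,
                       keepOrientation = keepOrientation, maxDist = maxDist,
                       promoterExclusion = promoterExclusion)
  v <- greedyPrune(fl$variants, minGap = minGap)
  counts <- c(window_off_end = ex$n_dropped, fl$drop_counts,
              pruned = nrow(fl$variants) - nrow(v))
  list(variants = v, drop_counts = counts)
}
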