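#' Synthetic chromatin-state segmentation with a matching genome
#'
#' Generates a small multi-chromosome genome together with a genome-tiling
#' chromatin-state segmentation and assembly-gap intervals, for exercising
#' the power simulations without reference segmentations. Recurrent
#' promoter-like clusters (TssFlnkU, TssA, TssFlnk, TssFlnkD, then Tx and
#' EnhBiv) are embedded in a quiescent (Quies) background, with occasional
#' gaps written as N runs.
#'
#' Two sequence regimes for the TSS-associated states:
#' \describe{
#'   \item{\code{"gc"}}{TSS states are GC-enriched (GC 0.55 vs 0.40
#'     background), so base composition alone separates them.}
#'   \item{\code{"cpg"}}{all states have the same uniform base composition
#'     (GC 0.5) but TSS states are generated from a first-order Markov
#'     chain with uniform stationary distribution and boosted CpG
#'     dinucleotide frequency -- GC content is uninformative there while
#'     2-mers and longer carry signal.}
#' }
#'
#' @param nChrom number of chromosomes (default 2).
#' @param chromLength length of each chromosome in bp (default 500000).
#' @param tssMode \code{"gc"} or \code{"cpg"} (see above).
#' @param clusterEvery spacing of promoter-like clusters in bp.
#' @param seed integer seed.
#' @return list with \code{genome} (\code{DNAStringSet}),
#'   \code{segmentation} (labeled \code{GRanges}) and \code{gaps}
#'   (\code{GRanges}).
#' @export
simulateSegmentedGenome <- function(nChrom = 2L, chromLength = 500000L,
                                    tssMode = c("gc", "cpg"),
                                    clusterEvery = 20000L, seed = 1L) {
  tssMode <- match.arg(tssMode)
  .withSeed(seed, {
    BASES <- c("A", "C", "G", "T")
    iid <- function(len, gc) sample(BASES, len, replace = TRUE,
                                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    # doubly stochastic transition matrix boosting CpG; stationary uniform
    cpgChain <- function(len, e = 0.15) {
      P <- matrix(0.25, 4, 4, dimnames = list(BASES, BASES))
      P["C", "G"] <- 0.25 + e; P["C", "A"] <- 0.25 - e
      P["A", "G"] <- 0.25 - e; P["A", "A"] <- 0.25 + e
      out <- integer(len)
      out[1L] <- sample.int(4L, 1L)
      for (i in seq_len(len - 1L))
        out[i + 1L] <- sample.int(4L, 1L, prob = P[out[i], ])
      BASES[out]
    }
    segChrom <- character(0); segStart <- integer(0); segEnd <- integer(0)
    segLab <- character(0)
    gapChrom <- character(0); gapStart <- integer(0); gapEnd <- integer(0)
    seqs <- character(nChrom)
    cluster <- c(TssFlnkU = 300L, TssA = 600L, TssFlnk = 300L,
                 TssFlnkD = 300L, Tx = 2000L, EnhBiv = 300L)
    for (ci in seq_len(nChrom)) {
      chr <- paste0("chr", ci)
      base <- iid(chromLength, if (tssMode == "gc") 0.40 else 0.50)
      pos <- clusterEvery %/% 2L
      k <- 0L
      while (pos + sum(cluster) < chromLength - 1000L) {
        at <- pos
        for (st in names(cluster)) {
          w <- cluster[[st]]
          gc <- switch(st, Tx = if (tssMode == "gc") 0.45 else 0.50,
                       EnhBiv = if (tssMode == "gc") 0.50 else 0.50,
                       if (tssMode == "gc") 0.55 else 0.50)
          tssState <- st %in% c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD")
          piece <- if (tssMode == "cpg" && tssState) cpgChain(w) else iid(w, gc)
          base[at:(at + w - 1L)] <- piece
          segChrom <- c(segChrom, chr); segStart <- c(segStart, at)
          segEnd <- c(segEnd, at + w - 1L); segLab <- c(segLab, st)
          at <- at + w
        }
        k <- k + 1L
        # an assembly gap after every fourth cluster
        if (k %% 4L == 0L) {
          gw <- 1000L
          base[at:(at + gw - 1L)] <- "N"
          gapChrom <- c(gapChrom, chr); gapStart <- c(gapStart, at)
          gapEnd <- c(gapEnd, at + gw - 1L)
          at <- at + gw
        }
        pos <- pos + clusterEvery
      }
      seqs[ci] <- paste(base, collapse = "")
    }
    names(seqs) <- paste0("chr", seq_len(nChrom))
    genome <- Biostrings::DNAStringSet(seqs)
    seg <- GenomicRanges::GRanges(segChrom,
                                  IRanges::IRanges(segStart, segEnd),
                                  label = segLab)
    # fill the remainder of each chromosome with Quies so the tiling is complete
    full <- GenomicRanges::GRanges(names(seqs),
                                   IRanges::IRanges(1L, chromLength))
    quies <- GenomicRanges::setdiff(full, seg, ignore.strand = TRUE)
    quies$label <- "Quies"
    seg <- GenomicRanges::sort(c(seg, quies), ignore.strand = TRUE)
    gaps <- if (length(gapChrom))
      GenomicRanges::GRanges(gapChrom, IRanges::IRanges(gapStart, gapEnd))
    else GenomicRanges::GRanges()
    list(genome = genome, segmentation = seg, gaps = gaps)
  })
}

# uniform positions over the union of 1-based closed intervals, by
# cumulative-length inversion
.samplePositions <- function(gr, n) {
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  w <- GenomicRanges::width(gr)
  if (sum(w) == 0L) stop("empty interval universe")
  cum <- cumsum(as.numeric(w))
  u <- ceiling(stats::runif(n) * cum[length(cum)])
  iv <- findInterval(u - 1L, cum) + 1L
  off <- u - c(0, cum)[iv]
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[iv],
             pos = GenomicRanges::start(gr)[iv] + as.integer(off) - 1L,
             stringsAsFactors = FALSE)
}

#' Simulate one dataset of chromatin-state-labeled variants
#'
#' Draws \code{nPerGroup} target-group and \code{nPerGroup} other-group
#' variant positions: round(X/100 * nPerGroup) target positions uniformly
#' from the union of the TSS-associated state intervals, all remaining
#' target positions and every other-group position uniformly genome-wide
#' excluding assembly gaps. Positions are kept at least 100 bp from
#' chromosome ends so every 201-bp window fits. All positions are then
#' greedily pruned so no two variants are closer than \code{minGap} bp;
#' the pruned deficit is refilled from the same pools and re-pruned (up to
#' 100 attempts) so group sizes stay exact.
#'
#' @param segmentation labeled \code{GRanges} segmentation.
#' @param gaps \code{GRanges} of assembly gaps to exclude.
#' @param X percent of target-group variants drawn from TSS states.
#' @param nPerGroup variants per group (the reference setting is 500).
#' @param tssStates the active TSS-associated state labels.
#' @param minGap pruning gap in bp (default 100).
#' @param chromLengths named integer vector of chromosome lengths.
#' @param seed optional integer seed.
#' @param margin positions are restricted to
#'   [margin + 1, length - margin] per chromosome (default 100).
#' @return data.frame with \code{variant_id}, \code{chrom}, \code{pos},
#'   \code{group} (\code{"target"}/\code{"other"}).
#' @export
simulateStateVariants <- function(segmentation, gaps, X, nPerGroup = 500L,
                                  tssStates = c("TssA", "TssFlnk",
                                                "TssFlnkU", "TssFlnkD"),
                                  minGap = 100L, chromLengths, seed = NULL,
                                  margin = 100L) {
  if (X < 0 || X > 100) stop("X must be in [0, 100]")
  tssIv <- segmentation[segmentation$label %in% tssStates]
  if (X > 0 && length(tssIv) == 0L)
    stop("requested TSS states absent from segmentation: ",
         paste(tssStates, collapse = ", "))
  full <- GenomicRanges::GRanges(names(chromLengths),
                                 IRanges::IRanges(margin + 1L,
                                                  chromLengths - margin))
  genomeWide <- GenomicRanges::setdiff(full, gaps, ignore.strand = TRUE)
  tssIv <- GenomicRanges::intersect(tssIv, full, ignore.strand = TRUE)
  nTss <- round(X / 100 * nPerGroup)
  .withSeed(seed, {
    draw <- function(nT, nBgT, nBgO) {
      parts <- list()
      if (nT > 0L) parts$tss <- cbind(.samplePositions(tssIv, nT),
                                      group = "target", pool = "tss")
      if (nBgT > 0L) parts$bgT <- cbind(.samplePositions(genomeWide, nBgT),
                                        group = "target", pool = "bg")
      if (nBgO > 0L) parts$bgO <- cbind(.samplePositions(genomeWide, nBgO),
                                        group = "other", pool = "bg")
      do.call(rbind, parts)
    }
    v <- draw(nTss, nPerGroup - nTss, nPerGroup)
    for (attempt in seq_len(100L)) {
      kept <- greedyPrune(v, minGap = minGap)
      defT_tss <- nTss - sum(kept$group == "target" & kept$pool == "tss")
      defT_bg <- (nPerGroup - nTss) -
        sum(kept$group == "target" & kept$pool == "bg")
      defO <- nPerGroup - sum(kept$group == "other")
      if (defT_tss + defT_bg + defO == 0L) {
        v <- kept
        break
      }
      v <- rbind(kept, draw(defT_tss, defT_bg, defO))
      if (attempt == 100L)
        stop("could not reach exact group sizes after 100 refill attempts")
    }
    v <- v[order(v$chrom, v$pos), c("chrom", "pos", "group")]
    v$variant_id <- sprintf("sv%04d", seq_len(nrow(v)))
    rownames(v) <- NULL
    v[, c("variant_id", "chrom", "pos", "group")]
  })
}

#' Power study over planted chromatin-state shifts
#'
#' For each X (percent of target variants drawn from TSS-associated
#' states) and each method (local GC content; multinomial Naive Bayes per
#' k-mer length), generates \code{nDatasets} simulated datasets, runs the
#' split-train-score test \code{splits} times per dataset, takes each
#' dataset's median one-sided test-fold p-value, and reports power as the
#' fraction of datasets whose median p falls below \code{threshold}.
#'
#' @param genome \code{DNAStringSet} matching the segmentation.
#' @param segmentation,gaps as in [simulateStateVariants()].
#' @param Xs vector of X values (the reference grid is
#'   \{10, 20, 50, 80, 100\}; include 0 for null calibration).
#' @param nPerGroup variants per group per dataset.
#' @param nDatasets datasets per X.
#' @param kValues k-mer lengths for the Naive Bayes method.
#' @param splits train/test split repetitions per dataset.
#' @param L window length (default 201).
#' @param threshold p-value threshold defining a detection (default 0.05).
#' @param seed master seed; all dataset and split seeds derive from it.
#' @return list with \code{power} (data.frame: X, method, power) and
#'   \code{median_p} (data.frame of per-dataset median p-values).
#' @export
runPowerStudy <- function(genome, segmentation, gaps, Xs = c(10, 20, 50, 80, 100),
                          nPerGroup = 500L, nDatasets = 50L, kValues = 1:7,
                          splits = 50L, L = 201L, threshold = 0.05,
                          seed = 1L) {
  chromLengths <- stats::setNames(Biostrings::width(genome), names(genome))
  methodsAll <- c("gc", paste0("nb_k", kValues))
  med <- list()
  for (xi in seq_along(Xs)) {
    X <- Xs[xi]
    for (d in seq_len(nDatasets)) {
      dseed <- (seed * 10007L + xi * 1009L + d * 101L) %% .Machine$integer.max
      v <- simulateStateVariants(segmentation, gaps, X = X,
                                 nPerGroup = nPerGroup,
                                 chromLengths = chromLengths, seed = dseed)
      ex <- suppressWarnings(extractWindows(genome, v, L = L))
      vv <- v[ex$keep, , drop = FALSE]
      gc <- localGcContent(ex$windows)
      labels <- vv$group
      kmerList <- lapply(kValues, function(k) kmerCounts(ex$windows, k))
      pmat <- matrix(NA_real_, splits, length(methodsAll),
                     dimnames = list(NULL, methodsAll))
      for (s in seq_len(splits)) {
        sseed <- dseed + s
        for (ki in seq_along(kValues)) {
          res <- kmerNeighborhoodTest(kmerList[[ki]], gc, labels,
                                      splitSeed = sseed, positive = "target")
          pmat[s, paste0("nb_k", kValues[ki])] <- res$nb$p
          if (ki == 1L) pmat[s, "gc"] <- res$gc$p
        }
      }
      med[[length(med) + 1L]] <- data.frame(
        X = X, dataset = d, method = methodsAll,
        median_p = apply(pmat, 2L, stats::median),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  medDf <- do.call(rbind, med)
  power <- stats::aggregate(median_p ~ X + method, data = medDf,
                            FUN = function(p) mean(p < threshold))
  names(power)[names(power) == "median_p"] <- "power"
  list(power = power, median_p = medDf)
}
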