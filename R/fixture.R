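#' Configuration for the synthetic input bundle
#'
#' Defaults describe a desk-scale analogue of a paired de novo WGS study:
#' a small multi-chromosome genome, a block-structured gene-gene expression
#' correlation matrix, families contributing one proband and one sibling
#' with around 19 de novo variants per child, sexes drawn with the cohort's
#' male-biased proband rate, and an optional planted GC-content shift
#' concentrated in proband variants assigned to one gene block.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length per-chromosome length in bp.
#' @param n_genes total genes (split evenly over chromosomes).
#' @param n_blocks correlation blocks (genes split evenly over blocks).
#' @param within_block_cor range of within-block correlations.
#' @param n_families number of proband/sibling families.
#' @param variants_per_child Poisson mean de novo count per child.
#' @param proband_male_rate,sibling_male_rate sex-draw probabilities.
#' @param planted_block index of the gene block carrying the planted
#'   effect (1-based).
#' @param delta planted shift, in expected GC-count units per 201-bp
#'   window, applied to proband variants assigned to the planted block
#'   (0 = null fixture).
#' @param gc_background background per-base GC probability.
#' @param lane_match_rate fraction of families whose proband and sibling
#'   share identical sequencing-lane metadata.
#' @param L window length the fixture is designed for.
#' @param seed integer seed; the bundle is byte-identical given the seed.
#' @return a list of class \code{fixture_config}.
#' @export
fixtureConfig <- function(n_chromosomes = 4L, chromosome_length = 250000L,
                          n_genes = 60L, n_blocks = 3L,
                          within_block_cor = c(0.6, 0.9),
                          n_families = 50L, variants_per_child = 19,
                          proband_male_rate = 0.87, sibling_male_rate = 0.47,
                          planted_block = 1L, delta = 0,
                          gc_background = 0.42, lane_match_rate = 0.8,
                          L = 201L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes > 0, cfg$chromosome_length > 0,
            cfg$n_genes > 0, cfg$n_families > 0, cfg$delta >= 0)
  if (cfg$n_genes %% (cfg$n_chromosomes) != 0)
    cfg$n_genes <- cfg$n_genes - cfg$n_genes %% cfg$n_chromosomes
  genesPerChrom <- cfg$n_genes / cfg$n_chromosomes
  if (cfg$chromosome_length < (genesPerChrom + 1) * 2000)
    stop("chromosome too short for requested gene count")
  class(cfg) <- "fixture_config"
  cfg
}

#' Generate the full synthetic input bundle on disk
#'
#' Writes, under \code{outDir}: \code{genome.fa} (region-controlled GC;
#' promoter-like high-GC islands at each TSS so the segmentation correlates
#' with the GC landscape), \code{tss.tsv} (both strands represented),
#' \code{corr.tsv} (block-structured), \code{variants.tsv} (paired
#' proband/sibling with sex and lane metadata; proband variants assigned to
#' the planted gene block sit in patches whose per-base GC probability is
#' raised so the expected window GC count shifts by \code{delta}),
#' \code{coding.bed} and \code{css.bed} (exclusion lists),
#' \code{segmentation.bed} (labeled, genome-tiling, GC-correlated) and
#' \code{manifest.json} recording the seed, the realized parameters and
#' the realized planted shift with its Monte-Carlo standard error.
#'
#' @param cfg a [fixtureConfig()] object.
#' @param outDir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
generateFixture <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  BASES <- c("A", "C", "G", "T")
  .withSeed(cfg$seed, {
    iid <- function(len, gc) sample(BASES, len, replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    lens <- stats::setNames(rep(cfg$chromosome_length, cfg$n_chromosomes), chroms)

    ## genes: evenly spaced TSSs, alternating strands, round-robin blocks
    genesPerChrom <- cfg$n_genes / cfg$n_chromosomes
    tss <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      at <- round(seq(cfg$chromosome_length / (genesPerChrom + 1),
                      cfg$chromosome_length * genesPerChrom / (genesPerChrom + 1),
                      length.out = genesPerChrom))
      data.frame(gene_id = sprintf("g%03d", (ci - 1L) * genesPerChrom +
                                     seq_len(genesPerChrom)),
                 chrom = chroms[ci], strand = rep(c("+", "-"),
                                                  length.out = genesPerChrom),
                 tss = as.integer(at), stringsAsFactors = FALSE)
    }))
    block <- rep(seq_len(cfg$n_blocks), length.out = cfg$n_genes)

    ## block-structured correlation matrix
    m <- matrix(stats::rnorm(cfg$n_genes^2, 0, 0.03), cfg$n_genes, cfg$n_genes)
    for (b in seq_len(cfg$n_blocks)) {
      idx <- which(block == b)
      m[idx, idx] <- stats::runif(length(idx)^2, cfg$within_block_cor[1L],
                                  cfg$within_block_cor[2L])
    }
    m <- (m + t(m)) / 2
    m <- pmin(pmax(m, -1), 1)
    diag(m) <- 1
    dimnames(m) <- list(tss$gene_id, tss$gene_id)

    ## genome with promoter-like high-GC islands at TSSs
    seqs <- lapply(chroms, function(chr) iid(cfg$chromosome_length,
                                             cfg$gc_background))
    names(seqs) <- chroms
    segRows <- list()
    for (i in seq_len(nrow(tss))) {
      a <- max(1L, tss$tss[i] - 1000L)
      b <- min(cfg$chromosome_length, tss$tss[i] + 1000L)
      seqs[[tss$chrom[i]]][a:b] <- iid(b - a + 1L, 0.55)
      segRows[[length(segRows) + 1L]] <-
        data.frame(chrom = tss$chrom[i], start = a - 1L, end = b,
                   label = "TssA", stringsAsFactors = FALSE)
      txa <- b + 1L; txb <- min(cfg$chromosome_length, b + 3000L)
      seqs[[tss$chrom[i]]][txa:txb] <- iid(txb - txa + 1L, 0.47)
      segRows[[length(segRows) + 1L]] <-
        data.frame(chrom = tss$chrom[i], start = txa - 1L, end = txb,
                   label = "Tx", stringsAsFactors = FALSE)
    }

    ## families, children, variants
    flank <- (cfg$L - 1L) / 2L
    famIds <- sprintf("f%03d", seq_len(cfg$n_families))
    probandSex <- ifelse(stats::runif(cfg$n_families) < cfg$proband_male_rate,
                         "male", "female")
    siblingSex <- ifelse(stats::runif(cfg$n_families) < cfg$sibling_male_rate,
                         "male", "female")
    laneMatched <- stats::runif(cfg$n_families) < cfg$lane_match_rate
    rows <- list()
    for (fi in seq_len(cfg$n_families)) {
      for (role in c("proband", "sibling")) {
        nv <- stats::rpois(1L, cfg$variants_per_child)
        if (nv == 0L) next
        repeat {  # resample until the child's (chrom, pos) draws are distinct
          chr <- sample(chroms, nv, replace = TRUE)
          pos <- as.integer(floor(stats::runif(nv, flank + 1L,
                                               cfg$chromosome_length - flank)))
          if (!anyDuplicated(paste(chr, pos))) break
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, pos = pos, family_id = famIds[fi], role = role,
          sex = if (role == "proband") probandSex[fi] else siblingSex[fi],
          lane_id = if (laneMatched[fi]) paste0("L", fi %% 8L) else
            paste0("L", fi %% 8L, if (role == "proband") "a" else "b"),
          stringsAsFactors = FALSE)
      }
    }
    variants <- do.call(rbind, rows)
    variants$variant_id <- sprintf("v%05d", seq_len(nrow(variants)))
    variants <- variants[, c("variant_id", "chrom", "pos", "family_id",
                             "role", "sex", "lane_id")]

    ## plant the GC shift: proband variants assigned to the planted block
    ## get a window-sized patch with raised per-base GC probability
    assigned <- assignToTss(variants, tss, maxDist = 100000L)
    plantedGenes <- tss$gene_id[block == cfg$planted_block]
    plantIdx <- which(assigned$role == "proband" &
                        !is.na(assigned$gene_id) &
                        assigned$gene_id %in% plantedGenes)
    pPlant <- min(1, cfg$gc_background + cfg$delta / cfg$L)
    if (cfg$delta > 0) {
      for (i in plantIdx) {
        a <- assigned$pos[i] - flank; b <- assigned$pos[i] + flank
        seqs[[assigned$chrom[i]]][a:b] <- iid(cfg$L, pPlant)
      }
    }

    ## small exclusion lists: a coding exon and two splice positions per gene
    coding <- data.frame(chrom = tss$chrom,
                         start = pmin(tss$tss + 4000L, lens[tss$chrom] - 400L),
                         stringsAsFactors = FALSE)
    coding$end <- coding$start + 300L
    css <- data.frame(chrom = rep(tss$chrom, each = 2L),
                      start = as.vector(rbind(coding$start - 1L, coding$end)),
                      stringsAsFactors = FALSE)
    css$end <- css$start + 1L

    ## write everything
    fa <- file.path(outDir, "genome.fa")
    writeLines(unlist(lapply(chroms, function(chr)
      c(paste0(">", chr), paste(seqs[[chr]], collapse = "")))), fa)
    writeTsv(variants, file.path(outDir, "variants.tsv"))
    writeTsv(tss, file.path(outDir, "tss.tsv"))
    corrOut <- cbind(data.frame(gene_id = rownames(m)),
                     as.data.frame(signif(m, 6)))
    utils::write.table(corrOut, file.path(outDir, "corr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(coding[, c("chrom", "start", "end")],
                       file.path(outDir, "coding.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(css[, c("chrom", "start", "end")],
                       file.path(outDir, "css.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    seg <- do.call(rbind, segRows)
    ## tile the remainder with Quies
    segGr <- GenomicRanges::GRanges(seg$chrom,
                                    IRanges::IRanges(seg$start + 1L, seg$end))
    full <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, lens))
    quies <- GenomicRanges::setdiff(full, segGr, ignore.strand = TRUE)
    segAll <- rbind(seg, data.frame(
      chrom = as.character(GenomicRanges::seqnames(quies)),
      start = GenomicRanges::start(quies) - 1L,
      end = GenomicRanges::end(quies), label = "Quies",
      stringsAsFactors = FALSE))
    segAll <- segAll[order(segAll$chrom, segAll$start), ]
    utils::write.table(segAll, file.path(outDir, "segmentation.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)

    ## realized planted shift and its Monte-Carlo standard error
    realized <- NA_real_; realizedSe <- NA_real_
    if (cfg$delta > 0 && length(plantIdx)) {
      g <- Biostrings::DNAStringSet(vapply(seq_along(chroms), function(ci)
        paste(seqs[[ci]], collapse = ""), ""))
      names(g) <- chroms
      w <- Biostrings::subseq(g[assigned$chrom[plantIdx]],
                              start = assigned$pos[plantIdx] - flank,
                              width = cfg$L)
      gcPlanted <- localGcContent(w)
      realized <- mean(gcPlanted) - cfg$L * cfg$gc_background
      realizedSe <- stats::sd(gcPlanted) / sqrt(length(gcPlanted))
    }
    manifest <- list(seed = cfg$seed,
                     config = unclass(cfg)[setdiff(names(cfg), "")],
                     n_variants = nrow(variants),
                     n_planted = if (cfg$delta > 0) length(plantIdx) else 0L,
                     planted_genes = plantedGenes,
                     realized_gc_shift = realized,
                     realized_gc_shift_se = realizedSe)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
  })
}
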