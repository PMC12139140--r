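sharedSeg <- NULL
getSeg <- function() {
  if (is.null(sharedSeg))
    sharedSeg <<- simulateSegmentedGenome(nChrom = 1, chromLength = 200000,
                                          tssMode = "gc", seed = 3)
  sharedSeg
}

test_that("segmentation tiles the genome and gaps are N runs", {
  sg <- getSeg()
  expect_equal(sum(GenomicRanges::width(sg$segmentation)), 200000)
  expect_true(all(c("TssA", "Quies", "Tx") %in% sg$segmentation$label))
  if (length(sg$gaps)) {
    gapSeq <- Biostrings::subseq(sg$genome[[1]],
                                 GenomicRanges::start(sg$gaps)[1],
                                 GenomicRanges::end(sg$gaps)[1])
    expect_equal(as.character(gapSeq),
                 strrep("N", GenomicRanges::width(sg$gaps)[1]))
  }
})

test_that("state draws honor X, gap exclusion and the pruning gap", {
  sg <- getSeg()
  lens <- setNames(Biostrings::width(sg$genome), names(sg$genome))

  # X = 100: every target position inside a TSS-associated state interval
  v100 <- simulateStateVariants(sg$segmentation, sg$gaps, X = 100,
                                nPerGroup = 60, chromLengths = lens,
                                seed = 5)
  tssIv <- sg$segmentation[sg$segmentation$label %in%
                             c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD")]
  tgt <- v100[v100$group == "target", ]
  gr <- GenomicRanges::GRanges(tgt$chrom, IRanges::IRanges(tgt$pos, tgt$pos))
  expect_true(all(IRanges::overlapsAny(gr, tssIv)))
  expect_equal(sum(v100$group == "target"), 60)
  expect_equal(sum(v100$group == "other"), 60)

  # no drawn position intersects a gap
  all100 <- GenomicRanges::GRanges(v100$chrom,
                                   IRanges::IRanges(v100$pos, v100$pos))
  expect_false(any(IRanges::overlapsAny(all100, sg$gaps)))

  # pruning: same-chromosome pairwise distances >= 100
  for (chr in unique(v100$chrom)) {
    p <- sort(v100$pos[v100$chrom == chr])
    if (length(p) > 1) expect_true(all(diff(p) >= 100))
  }

  # X = 0: both groups from the same genome-wide distribution; group sizes exact
  v0 <- simulateStateVariants(sg$segmentation, sg$gaps, X = 0,
                              nPerGroup = 80, chromLengths = lens, seed = 6)
  expect_equal(as.vector(table(v0$group)), c(80, 80))
  expect_error(simulateStateVariants(sg$segmentation[sg$segmentation$label ==
                                                       "Quies"],
                                     sg$gaps, X = 50, nPerGroup = 10,
                                     chromLengths = lens, seed = 1),
               "absent")
  # determinism
  vA <- simulateStateVariants(sg$segmentation, sg$gaps, X = 50,
                              nPerGroup = 50, chromLengths = lens, seed = 9)
  vB <- simulateStateVariants(sg$segmentation, sg$gaps, X = 50,
                              nPerGroup = 50, chromLengths = lens, seed = 9)
  expect_identical(vA, vB)
})

test_that("fixture bundles are complete, byte-reproducible and shift-calibrated", {
  cfg <- fixtureConfig(n_chromosomes = 2, chromosome_length = 120000,
                       n_genes = 20, n_families = 20, delta = 10, seed = 41)
  d1 <- file.path(tempdir(), "fxA"); d2 <- file.path(tempdir(), "fxB")
  man1 <- generateFixture(cfg, d1)
  man2 <- generateFixture(cfg, d2)
  files <- c("genome.fa", "variants.tsv", "tss.tsv", "corr.tsv",
             "coding.bed", "css.bed", "segmentation.bed", "manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # realized planted shift within Monte-Carlo error of delta
  expect_gt(man1$n_planted, 10)
  expect_lt(abs(man1$realized_gc_shift - 10), 4 * man1$realized_gc_shift_se)
  # the bundle round-trips through the readers
  g <- readGenomeFasta(file.path(d1, "genome.fa"))
  expect_equal(length(g), 2L)
  v <- readVariantTable(file.path(d1, "variants.tsv"))
  expect_equal(nrow(v), man1$n_variants)
  corr <- readCorrelationMatrix(file.path(d1, "corr.tsv"))
  expect_equal(length(geneIds(corr)), 20L)
  tss <- readTssTable(file.path(d1, "tss.tsv"))
  expect_true(all(c("+", "-") %in% tss$strand))
  seg <- readIntervalAnnotations(file.path(d1, "segmentation.bed"),
                                 labeled = TRUE)
  expect_equal(sum(GenomicRanges::width(seg)), 2 * 120000)
})

test_that("a null fixture yields no permutation discoveries end to end", {
  cfg <- fixtureConfig(n_chromosomes = 2, chromosome_length = 120000,
                       n_genes = 20, n_families = 30, delta = 0, seed = 57)
  d <- file.path(tempdir(), "fxNull")
  generateFixture(cfg, d)
  g <- readGenomeFasta(file.path(d, "genome.fa"))
  v <- readVariantTable(file.path(d, "variants.tsv"))
  tss <- readTssTable(file.path(d, "tss.tsv"))
  corr <- readCorrelationMatrix(file.path(d, "corr.tsv"))
  prep <- prepareVariants(v, g, tss, L = 201, maxDist = 100000)
  pv <- prep$variants
  nbhds <- lapply(geneIds(corr), buildNeighborhood, corr = corr,
                  variants = pv, M = 100)
  gcVals <- setNames(pv$gc_count, pv$variant_id)
  labels <- setNames(pv$role, pv$variant_id)
  fams <- setNames(pv$family_id, pv$variant_id)
  obs <- neighborhoodGcTests(nbhds, gcVals, labels, positive = "proband")
  permP <- permutationPvalues(nbhds, gcVals, labels, fams, B = 100, seed = 8)
  res <- permutationFdr(obs$p, permP)
  expect_equal(res$n_discoveries, 0L)
})

test_that("the power study is calibrated at X = 0 and detects planted CpG signal", {
  sg <- simulateSegmentedGenome(nChrom = 1, chromLength = 300000,
                                tssMode = "cpg", seed = 19)
  ps <- runPowerStudy(sg$genome, sg$segmentation, sg$gaps, Xs = c(0, 100),
                      nPerGroup = 100, nDatasets = 6, kValues = 2,
                      splits = 6, seed = 23)
  p0 <- ps$power[ps$power$X == 0, ]
  expect_true(all(p0$power <= 0.5))  # small-n sanity, not the calibration claim
  nb100 <- ps$power$power[ps$power$X == 100 & ps$power$method == "nb_k2"]
  gc100 <- ps$power$power[ps$power$X == 100 & ps$power$method == "gc"]
  expect_gte(nb100, gc100)
  expect_gte(nb100, 0.5)
})
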