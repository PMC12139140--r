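test_that("window extraction is centered, bounded and matches direct slicing", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AAACAAA"))
  expect_equal(extractWindow(g, "chr1", 4, 3), "ACA")
  expect_error(extractWindow(g, "chr1", 1, 3), "off chromosome end")

  gr <- randomGenome(c(chr1 = 1000L), seed = 42)
  names(gr) <- "chr1"
  w <- extractWindow(gr, "chr1", 500, 201)
  # independent oracle: 0-based slice [399, 600) of the raw string
  expect_equal(w, substr(as.character(gr[["chr1"]]), 400, 600))
  expect_equal(nchar(w), 201L)
})

test_that("vectorized extraction drops off-end windows with a count", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100), collapse = "")))
  v <- toyVariants("chr1", c(1L, 200L, 399L))
  expect_warning(res <- extractWindows(g, v, L = 201), "2 variant")
  expect_equal(res$n_dropped, 2L)
  expect_equal(as.character(res$windows[[1]]),
               extractWindow(g, "chr1", 200, 201))
})

test_that("local GC content counts G/C and treats N as non-GC", {
  expect_equal(localGcContent(strrep("G", 201)), 201L)
  expect_equal(localGcContent(strrep("AT", 100)), 0L)
  expect_equal(localGcContent("GCATN"), 2L)
  # complement identity: GC + AT + N == window length
  set.seed(7)
  w <- paste(sample(c("A", "C", "G", "T", "N"), 201, replace = TRUE),
             collapse = "")
  ds <- Biostrings::DNAStringSet(w)
  atn <- as.integer(Biostrings::letterFrequency(ds, "ATN"))
  expect_equal(localGcContent(w) + atn, 201L)
})

test_that("k-mer counts are lexicographic and skip N-containing k-mers", {
  m <- kmerCounts("ACGT", 2)
  expect_equal(as.integer(m[1, c("AC", "CG", "GT")]), c(1L, 1L, 1L))
  expect_equal(sum(m), 3L)

  set.seed(1)
  w <- paste(sample(c("A", "C", "G", "T"), 201, replace = TRUE), collapse = "")
  expect_equal(sum(kmerCounts(w, 6)), 196L)  # 201 - 6 + 1

  m2 <- kmerCounts("ACNGT", 2)
  expect_equal(as.integer(m2[1, c("AC", "GT")]), c(1L, 1L))
  expect_equal(sum(m2), 2L)

  # k = 1 recovers base tallies; G + C equals local GC for N-free windows
  m1 <- kmerCounts(w, 1)
  expect_equal(sum(m1[1, c("G", "C")]), localGcContent(w))
  expect_equal(sum(m1), nchar(w))
})

test_that("TSS assignment picks the nearest gene within the radius", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 5000L, stringsAsFactors = FALSE)
  v <- assignToTss(toyVariants("chr1", 4000L), tss)
  expect_equal(v$gene_id, "g1")
  expect_equal(abs(v$tss_distance), 1000L)
  expect_equal(v$orientation, "upstream")

  far <- assignToTss(toyVariants("chr1", 155001L), tss)
  expect_equal(far$orientation, "unassigned")
  expect_true(is.na(far$gene_id))

  tss2 <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                     strand = "+", tss = c(1000L, 2000L),
                     stringsAsFactors = FALSE)
  mid <- assignToTss(toyVariants("chr1", 1499L), tss2)
  expect_equal(mid$gene_id, "gA")  # |499| < |501|
})

test_that("TSS assignment agrees with a brute-force scan on random fixtures", {
  set.seed(11)
  for (rep in 1:10) {
    tss <- data.frame(gene_id = sprintf("g%02d", 1:8),
                      chrom = sample(c("chr1", "chr2"), 8, replace = TRUE),
                      strand = sample(c("+", "-"), 8, replace = TRUE),
                      tss = sample.int(50000L, 8), stringsAsFactors = FALSE)
    v <- toyVariants(sample(c("chr1", "chr2"), 30, replace = TRUE),
                     sample.int(60000L, 30))
    got <- assignToTss(v, tss, maxDist = 10000L)
    for (i in seq_len(nrow(v))) {
      cand <- tss[tss$chrom == v$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0L) { expect_true(is.na(got$gene_id[i])); next }
      d <- abs(v$pos[i] - cand$tss)
      best <- cand$gene_id[order(d, cand$gene_id)][1]
      if (min(d) > 10000L) expect_true(is.na(got$gene_id[i]))
      else expect_equal(got$gene_id[i], best)
    }
  }
})

test_that("upstream classification is strand-aware with ties downstream", {
  expect_equal(classifyUpstream(4000, 5000, "+"), "upstream")
  expect_equal(classifyUpstream(6000, 5000, "-"), "upstream")
  expect_equal(classifyUpstream(5000, 5000, "+"), "downstream")
  expect_equal(classifyUpstream(5000, 5000, "-"), "downstream")
  expect_equal(classifyUpstream(6000, 5000, "+"), "downstream")
})

test_that("filters drop in order with audit counts and strict promoter rule", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 10000L, stringsAsFactors = FALSE)
  v <- assignToTss(toyVariants("chr1", c(500L, 8001L, 8000L, 12000L)), tss)
  coding <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400, 600))
  res <- filterVariants(v, exclusions = list(coding = coding),
                        keepOrientation = "upstream", maxDist = 100000L,
                        promoterExclusion = 2000L)
  expect_equal(unname(res$drop_counts["coding"]), 1L)      # variant at 500
  expect_equal(unname(res$drop_counts["orientation"]), 1L) # variant at 12000
  # 8001 is 1999 bp upstream (< 2000, dropped); 8000 is exactly 2000 (kept)
  expect_equal(unname(res$drop_counts["promoter"]), 1L)
  expect_equal(res$variants$pos, 8000L)
})

test_that("greedy pruning keeps the smaller coordinate per close pair", {
  v <- toyVariants("chr1", c(100L, 150L, 250L))
  expect_equal(greedyPrune(v, 101L)$pos, c(100L, 250L))

  spaced <- toyVariants("chr1", c(100L, 300L, 500L))
  expect_equal(greedyPrune(spaced, 101L)$pos, spaced$pos)

  two <- rbind(toyVariants("chr1", c(100L, 150L)),
               toyVariants("chr2", c(100L, 150L), variant_id = c("w1", "w2")))
  pruned <- greedyPrune(two, 101L)
  expect_equal(table(pruned$chrom)[["chr1"]], 1L)
  expect_equal(table(pruned$chrom)[["chr2"]], 1L)

  # invariant: all same-chromosome pairwise distances >= minGap
  set.seed(3)
  big <- toyVariants(sample(c("chr1", "chr2"), 200, replace = TRUE),
                     sample.int(5000L, 200))
  out <- greedyPrune(big, 101L)
  for (chr in unique(out$chrom)) {
    p <- sort(out$pos[out$chrom == chr])
    if (length(p) > 1L) expect_true(all(diff(p) >= 101L))
  }
})

test_that("stratification filters by sex combination and lane tuples", {
  v <- rbind(
    toyVariants("chr1", 1:2 * 100L, family_id = "f1",
                role = c("proband", "sibling"), sex = c("male", "female"),
                variant_id = c("a1", "a2")),
    toyVariants("chr1", 3:4 * 100L, family_id = "f2",
                role = c("proband", "sibling"), sex = c("male", "male"),
                variant_id = c("b1", "b2")),
    toyVariants("chr1", 5:6 * 100L, family_id = "f3",
                role = c("proband", "sibling"), sex = c("female", "female"),
                variant_id = c("c1", "c2")))
  mf <- stratifyVariants(v, probandSex = "male", siblingSex = "female")
  expect_equal(unique(mf$family_id), "f1")

  v$lane_a <- c("L1", "L1", "L2", "L3", "L4", "L4")
  v$lane_b <- c("P1", "P1", "P2", "P2", "P3", "P3")
  expect_equal(unique(stratifyVariants(v, laneMatch = "match")$family_id),
               c("f1", "f3"))
  expect_equal(unique(stratifyVariants(v, laneMatch = "mismatch")$family_id),
               "f2")
  v2 <- v[, setdiff(names(v), c("lane_a", "lane_b"))]
  expect_error(stratifyVariants(v2, laneMatch = "match"), "no lane")
})
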