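# exhaustive pair-counting oracle for the Mann-Whitney U statistic
bruteU <- function(target, other) {
  u <- 0
  for (x in target) for (y in other)
    u <- u + (x > y) + 0.5 * (x == y)
  u
}

test_that("U statistic and p-value behave at the symmetric and extreme cases", {
  res <- mwuTest(c(1, 2), c(1, 2), sided = "one")
  expect_equal(res$U, 2)  # n*m/2
  expect_lt(abs(res$p - 0.5), 0.2)  # approximation is loose at n = 2

  res2 <- mwuTest(3, c(1, 2), sided = "one")
  expect_equal(res2$U, 2)
  # exact enumeration over the 3 placements of the target rank: p = 1/3
  expect_lt(abs(res2$p - 1 / 3), 0.08)

  res3 <- mwuTest(c(1, 2), c(3, 4), sided = "one")
  expect_equal(res3$U, 0)
  expect_gt(res3$p, 0.5)
  expect_error(mwuTest(numeric(0), 1), "non-empty")
})

test_that("U equals exhaustive pair counting and p matches wilcox.test", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- sample(0:20, n1, replace = TRUE)
    y <- sample(0:20, n2, replace = TRUE)
    res <- mwuTest(x, y, sided = "one")
    expect_equal(res$U, bruteU(x, y))
    # independent route: stats::wilcox.test normal approximation
    w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                             exact = FALSE, correct = TRUE))
    expect_equal(res$p, w$p.value, tolerance = 1e-12)
    res2 <- mwuTest(x, y, sided = "two")
    w2 <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    expect_equal(res2$p, w2$p.value, tolerance = 1e-12)
  }
})

test_that("Naive Bayes training applies Laplace smoothing with uniform priors", {
  x <- rbind(c(0, 5, 5, 0), c(5, 0, 0, 5))
  colnames(x) <- c("A", "C", "G", "T")
  model <- nbTrain(x, c("positive", "negative"), alpha = 1,
                   positive = "positive")
  expect_equal(exp(classLogProbs(model)["positive", ]),
               c(A = 1, C = 6, G = 6, T = 1) / 14, tolerance = 1e-12)
  expect_equal(exp(classLogProbs(model)["negative", ]),
               c(A = 6, C = 1, G = 1, T = 6) / 14, tolerance = 1e-12)
  expect_error(nbTrain(x, c("positive", "negative"), alpha = 0), "alpha")
  expect_error(nbTrain(x, c("positive", "positive")), "two classes")

  # identical totals per class give identical word probabilities
  x2 <- rbind(c(2, 3, 1, 0), c(2, 3, 1, 0))
  m2 <- nbTrain(x2, c("positive", "negative"), positive = "positive")
  expect_equal(classLogProbs(m2)["positive", ],
               classLogProbs(m2)["negative", ])
})

test_that("posterior scores follow the two-class closed form", {
  x <- rbind(c(0, 5, 5, 0), c(5, 0, 0, 5))
  model <- nbTrain(x, c("positive", "negative"), positive = "positive")
  # one C: posterior = theta_P[C] / (theta_P[C] + theta_N[C]) = 6/7
  expect_equal(nbScore(model, c(0, 1, 0, 0)), 6 / 7, tolerance = 1e-12)
  expect_equal(nbScore(model, c(0, 0, 0, 0)), 0.5)  # likelihoods cancel
  m2 <- nbTrain(rbind(c(1, 1, 1, 1), c(1, 1, 1, 1)),
                c("positive", "negative"), positive = "positive")
  expect_equal(nbScore(m2, c(3, 0, 2, 9)), 0.5)

  # k = 1 decision score is monotone in GC count when theta favors G/C in
  # the positive class
  gcRich <- vapply(0:4, function(g)
    nbScore(model, c(4 - g, ceiling(g / 2), floor(g / 2), 0)), 0)
  expect_true(all(diff(gcRich) > 0))
})

test_that("split-train-score test is deterministic and fold-stratified", {
  set.seed(2)
  km <- matrix(rpois(40, 5), nrow = 10)
  km <- cbind(km, matrix(0, 10, 0))[, 1:4]
  gc <- rpois(10, 90)
  labels <- rep(c("proband", "sibling"), 5)
  r1 <- kmerNeighborhoodTest(km, gc, labels, splitSeed = 99)
  r2 <- kmerNeighborhoodTest(km, gc, labels, splitSeed = 99)
  expect_identical(r1$fold, r2$fold)
  expect_identical(r1$nb$p, r2$nb$p)
  expect_identical(r1$gc$p, r2$gc$p)
  # stratified: per class the folds differ in size by at most one
  for (cl in unique(labels)) {
    sizes <- table(r1$fold[labels == cl])
    expect_lte(abs(sizes[["1"]] - sizes[["2"]]), 1)
  }
  expect_error(kmerNeighborhoodTest(km[1:3, ], gc[1:3], labels[1:3], 1),
               ">= 2 variants")
})

test_that("per-k-mer binomial tests match the closed-form tails", {
  # all 10 occurrences in the target group at p0 = 0.5: p = 2 * 0.5^10
  km <- rbind(matrix(c(10, 0, 0, 0), 1), matrix(0, 1, 4))
  colnames(km) <- c("AA", "AC", "AG", "AT")
  res <- perKmerBinomial(km, c("proband", "sibling"), positive = "proband")
  expect_equal(res$p[res$kmer == "AA"], 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(res$p[res$kmer == "AC"], 1)  # absent everywhere

  # balanced occurrences at the null center: p = 1
  km2 <- rbind(c(5, 0, 0, 0), c(5, 0, 0, 0))
  res2 <- perKmerBinomial(km2, c("proband", "sibling"), positive = "proband")
  expect_equal(res2$p[1], 1)
})

test_that("GC score adjustment subtracts leave-one-out class means", {
  expect_equal(adjustScoreForGc(c(2, 2, 2), c(90, 90, 90)), c(0, 0, 0))
  expect_equal(adjustScoreForGc(c(1, 3), c(80, 80)), c(-2, 2))
  expect_equal(adjustScoreForGc(7, 100), 7)  # singleton class untouched

  # random fixtures against a direct leave-one-out oracle
  set.seed(13)
  for (i in 1:10) {
    s <- rnorm(40)
    g <- sample(85:90, 40, replace = TRUE)
    adj <- adjustScoreForGc(s, g)
    for (j in seq_along(s)) {
      peers <- setdiff(which(g == g[j]), j)
      expected <- if (length(peers)) s[j] - mean(s[peers]) else s[j]
      expect_equal(adj[j], expected)
    }
  }
})

test_that("variant-set tests apply BH across sets and skip one-group sets", {
  ids <- sprintf("v%02d", 1:40)
  values <- setNames(rnorm(40), ids)
  labels <- setNames(rep(c("proband", "sibling"), 20), ids)
  sets <- list(s1 = ids[1:10], s2 = ids[11:30], s3 = ids[31:40])
  res <- variantSetTest(sets, values, labels, sided = "two")
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  expect_equal(nrow(res), 3L)

  one <- list(only = ids[1:10])
  r1 <- variantSetTest(one, values, labels, sided = "two")
  expect_equal(r1$q, r1$p)

  badSet <- list(s = c(ids[1:4], "missing"))
  expect_error(variantSetTest(badSet, values, labels), "unknown variant ids")
  oneGroup <- list(allP = ids[seq(1, 9, 2)], ok = ids[1:10])
  expect_warning(r2 <- variantSetTest(oneGroup, values, labels),
                 "only one group")
  expect_equal(nrow(r2), 1L)
})

test_that("BH step-up reproduces the hand-computed q-values", {
  # independent hand computation: {0.01,0.02,0.04} -> {0.03,0.03,0.04}
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("Bonferroni thresholds reproduce the reference settings", {
  expect_equal(signif(bonferroniThreshold(0.05, 29820), 2), 1.7e-6)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 4^6), 1.2207e-5, tolerance = 1e-4)
})

test_that("within-pair label swapping preserves family totals", {
  fams <- rep(sprintf("f%02d", 1:10), each = 4)
  labels <- rep(c("proband", "proband", "sibling", "sibling"), 10)
  r1 <- permutePairLabels(labels, fams, seed = 5)
  r2 <- permutePairLabels(labels, fams, seed = 5)
  expect_identical(r1$labels, r2$labels)
  for (f in unique(fams)) {
    before <- table(labels[fams == f])
    after <- table(r1$labels[fams == f])
    expect_equal(as.vector(before), as.vector(after))
  }
  expect_error(permutePairLabels(rep("proband", 4), rep("f1", 4)),
               "two roles")
  expect_error(
    permutePairLabels(c("proband", "proband", "sibling"), c("f1", "f2", "f2")),
    "missing a role")

  # swap frequency: each family swapped in 50% +- 3% over 2000 permutations
  set.seed(123)
  counts <- numeric(10)
  for (b in 1:2000) {
    r <- permutePairLabels(labels, fams)
    counts <- counts + r$swapped
  }
  expect_true(all(abs(counts / 2000 - 0.5) < 0.03))
})

test_that("batched permutation p-values equal per-permutation recomputation", {
  fx <- nullNeighborhoodFixture(nNbhd = 4, famPerNbhd = 12, seed = 8)
  B <- 25
  pm <- permutationPvalues(fx$neighborhoods, fx$gc, fx$labels, fx$families,
                           B = B, seed = 42, positive = "proband")
  expect_equal(dim(pm), c(B, 4))
  # independent route: regenerate the same swaps and run mwuTest per cell
  set.seed(42)
  fams <- sort(unique(fx$families))
  swap <- matrix(runif(length(fams) * B) < 0.5, length(fams), B)
  rownames(swap) <- fams
  for (b in c(1, 7, 25)) for (j in 1:4) {
    ids <- fx$neighborhoods[[j]]
    lab <- fx$labels[ids]
    flip <- swap[fx$families[ids], b]
    permLab <- ifelse(flip, ifelse(lab == "proband", "sibling", "proband"), lab)
    ref <- mwuTest(fx$gc[ids][permLab == "proband"],
                   fx$gc[ids][permLab == "sibling"], sided = "one")
    expect_equal(pm[b, j], ref$p, tolerance = 1e-12)
  }
})

test_that("permutation FDR walks candidate thresholds as defined", {
  # hand-walked case: at T = 0.5 one discovery but 1.5 estimated false
  # positives (FDR 1.5); at T = 0.001 zero strict discoveries -> no threshold
  observed <- c(0.001, 0.5)
  permuted <- matrix(0.6, nrow = 20, ncol = 2)
  permuted[1:15, 1] <- 0.3          # 15 of 40 entries below 0.5
  permuted[1:15, 2] <- 0.45
  res <- permutationFdr(observed, permuted, targetFdr = 0.05)
  expect_true(is.na(res$threshold))
  expect_equal(res$n_discoveries, 0L)
  expect_false(any(res$significant))

  # a clean positive case: all permuted p-values sit above every observed
  observed2 <- c(1e-6, 0.2, 0.9)
  permuted2 <- matrix(0.95, nrow = 10, ncol = 3)
  res2 <- permutationFdr(observed2, permuted2, targetFdr = 0.05)
  expect_equal(res2$threshold, 0.9)
  expect_equal(res2$n_discoveries, 2L)
  expect_equal(res2$significant, c(TRUE, TRUE, FALSE))
  expect_equal(res2$estimated_fdr, 0)

  # no signal: observed drawn from the permutation distribution itself
  set.seed(4)
  obs3 <- runif(50)
  perm3 <- matrix(runif(50 * 100), 100, 50)
  res3 <- permutationFdr(obs3, perm3)
  expect_equal(res3$n_discoveries, 0L)

  # independent loop recomputation of the estimated-FDR curve
  for (T in sort(unique(obs3))[c(1, 10, 25)]) {
    disc <- sum(obs3 < T)
    fp <- sum(perm3 < T) / nrow(perm3)
    if (disc > 0) {
      resT <- permutationFdr(obs3, perm3, targetFdr = fp / disc + 1e-9)
      expect_false(is.na(resT$threshold))
      expect_gte(resT$threshold, T)
    }
  }
  expect_error(permutationFdr(c(0.1, 0.2), matrix(1, 2, 3)), "one column")
})
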