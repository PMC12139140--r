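#' Mann-Whitney U rank test
#'
#' U is computed exactly by midrank assignment; the p-value uses the
#' normal approximation with tie correction and continuity correction (the
#' standard large-sample route; neighborhoods hold on the order of a
#' thousand variants, where the approximation is conventional). The
#' one-sided alternative is that \code{target} is stochastically greater
#' than \code{other}.
#'
#' @param target,other numeric value vectors for the two groups.
#' @param sided \code{"one"} or \code{"two"}.
#' @return list with \code{U} (statistic for the target group), \code{p},
#'   \code{n_target}, \code{n_other}, \code{sided}.
#' @export
mwuTest <- function(target, other, sided = c("one", "two")) {
  sided <- match.arg(sided)
  n1 <- length(target); n2 <- length(other)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  all <- c(target, other)
  r <- rank(all)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(all)
  tieTerm <- sum(ties^3 - ties)
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1))))
  mu <- n1 * n2 / 2
  if (sigma == 0) {
    p <- 1
  } else if (sided == "one") {
    p <- stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
  } else {
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(U = U, p = p, n_target = n1, n_other = n2, sided = sided)
}

.defaultPositive <- function(labels) {
  if ("proband" %in% labels) "proband" else sort(unique(labels))[1L]
}

#' Train a multinomial Naive Bayes k-mer classifier
#'
#' Uniform class priors; per-class word probabilities use Laplace
#' smoothing: theta[c, w] = (N[c, w] + alpha) / (N[c] + alpha * 4^k) where
#' N[c, w] is the summed count of k-mer w over the training variants of
#' class c. \code{alpha} must be strictly positive so that no word
#' probability is zero.
#'
#' @param x integer matrix of k-mer counts (rows = variants, 4^k columns).
#' @param labels class label per row; exactly two classes must be present.
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @param positive label of the positive (target) class; defaults to
#'   \code{"proband"} when present, else the alphabetically first label.
#' @return a \linkS4class{NaiveBayesModel}.
#' @export
nbTrain <- function(x, labels, alpha = 1, positive = .defaultPositive(labels)) {
  if (alpha <= 0) stop("alpha must be > 0")
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("training data must contain exactly two classes, got ",
         length(classes))
  if (!positive %in% classes) stop("positive class absent from labels")
  negative <- setdiff(classes, positive)
  k <- as.integer(round(log(ncol(x), 4)))
  if (4L^k != ncol(x)) stop("feature count is not a power of 4")
  Np <- colSums(x[labels == positive, , drop = FALSE])
  Nn <- colSums(x[labels == negative, , drop = FALSE])
  logTheta <- rbind(log(Np + alpha) - log(sum(Np) + alpha * ncol(x)),
                    log(Nn + alpha) - log(sum(Nn) + alpha * ncol(x)))
  rownames(logTheta) <- c(positive, negative)
  methods::new("NaiveBayesModel", k = k, logTheta = logTheta,
               classes = c(positive, negative), alpha = alpha)
}

#' Posterior probability of the positive class
#'
#' score = softmax over per-class log-likelihood plus log-prior; with
#' uniform priors these cancel and the score depends only on the
#' likelihood ratio. An all-zero count vector therefore scores 0.5.
#'
#' @param model a \linkS4class{NaiveBayesModel}.
#' @param x k-mer count matrix (or single count vector) with 4^k columns.
#' @return numeric vector of positive-class posteriors in (0, 1).
#' @export
nbScore <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(model@logTheta))
    stop("count vector length must be 4^k")
  ll <- x %*% t(model@logTheta)  # n x 2 log-likelihoods
  d <- ll[, 2L] - ll[, 1L]       # log LR negative/positive
  as.numeric(1 / (1 + exp(d)))
}

#' Split-train-score k-mer test for one neighborhood
#'
#' The neighborhood's variants are split into evenly sized training and
#' testing folds (stratified by class so both folds contain both classes;
#' per-class fold sizes differ by at most one). A multinomial Naive Bayes
#' model is trained on the training fold; test-fold variants are scored and
#' a one-sided Mann-Whitney U test asks whether the positive group scores
#' higher. For comparability, the local-GC test is run on the identical
#' test fold.
#'
#' @param kmers k-mer count matrix over the neighborhood's variants.
#' @param gc local GC counts, parallel to \code{kmers} rows.
#' @param labels group label per variant.
#' @param splitSeed integer seed controlling the random split.
#' @param alpha Laplace smoothing for the classifier.
#' @param stratified stratify the split by class (default TRUE); with
#'   unstratified splitting a test fold missing a class is an error.
#' @param positive the target class label.
#' @return list with \code{nb} and \code{gc} rank-test results (see
#'   [mwuTest()]) and \code{fold} (1 = train, 2 = test per variant).
#' @export
kmerNeighborhoodTest <- function(kmers, gc, labels, splitSeed,
                                 alpha = 1, stratified = TRUE,
                                 positive = .defaultPositive(labels)) {
  n <- nrow(kmers)
  if (length(gc) != n || length(labels) != n)
    stop("kmers, gc and labels must be parallel")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes required")
  if (min(table(labels)) < 2L) stop("need >= 2 variants per class")
  fold <- integer(n)
  rng <- .withSeed(splitSeed, {
    if (stratified) {
      for (cl in classes) {
        idx <- which(labels == cl)
        nTrain <- floor(length(idx) / 2)
        train <- sample(idx, nTrain)
        fold[idx] <- 2L
        fold[train] <- 1L
      }
    } else {
      train <- sample(n, floor(n / 2))
      fold[] <- 2L
      fold[train] <- 1L
    }
    fold
  })
  fold <- rng
  if (length(unique(labels[fold == 2L])) < 2L ||
      length(unique(labels[fold == 1L])) < 2L)
    stop("a fold is missing a class; use stratified splitting")
  model <- nbTrain(kmers[fold == 1L, , drop = FALSE], labels[fold == 1L],
                   alpha = alpha, positive = positive)
  scores <- nbScore(model, kmers[fold == 2L, , drop = FALSE])
  testLabels <- labels[fold == 2L]
  nb <- mwuTest(scores[testLabels == positive],
                scores[testLabels != positive], sided = "one")
  gcRes <- mwuTest(gc[fold == 2L][testLabels == positive],
                   gc[fold == 2L][testLabels != positive], sided = "one")
  list(nb = nb, gc = gcRes, fold = fold)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Per-k-mer two-sided binomial prevalence tests
#'
#' For each k-mer w: x = total occurrences of w in target-group windows,
#' n = total occurrences in all windows, null success probability p0 = the
#' proportion of variants in the target group. Exact two-sided binomial
#' test; a k-mer absent everywhere gets p = 1. Significance is flagged at
#' the Bonferroni threshold alpha / 4^k.
#'
#' @param kmers k-mer count matrix.
#' @param labels group label per row.
#' @param positive target class label.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.frame with columns \code{kmer}, \code{x}, \code{n},
#'   \code{p}, \code{significant}.
#' @export
perKmerBinomial <- function(kmers, labels, positive = .defaultPositive(labels),
                            alpha = 0.05) {
  if (length(unique(labels)) != 2L) stop("exactly two classes required")
  isT <- labels == positive
  if (!any(isT) || all(isT)) stop("both groups must be non-empty")
  if (is.null(colnames(kmers))) {
    k <- as.integer(round(log(ncol(kmers), 4)))
    colnames(kmers) <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  }
  x <- colSums(kmers[isT, , drop = FALSE])
  n <- colSums(kmers)
  p0 <- sum(isT) / length(isT)
  p <- vapply(seq_along(n), function(j) {
    if (n[j] == 0) return(1)
    stats::binom.test(x[j], n[j], p = p0, alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(kmer = colnames(kmers), x = as.integer(x), n = as.integer(n),
             p = p, significant = p <= alpha / ncol(kmers),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjust an external per-variant score for local GC content
#'
#' From each variant's score, subtract the mean score of all \emph{other}
#' variants with exactly the same GC count (leave-one-out class mean).
#' Variants whose GC count is unique have nothing comparable and are left
#' unchanged.
#'
#' @param scores numeric per-variant scores (e.g. a disease impact score).
#' @param gcCounts integer per-variant local GC counts, parallel.
#' @return numeric vector of adjusted scores.
#' @export
adjustScoreForGc <- function(scores, gcCounts) {
  if (length(scores) != length(gcCounts)) stop("scores and gcCounts must align")
  out <- scores
  for (idx in split(seq_along(scores), gcCounts)) {
    if (length(idx) < 2L) next
    s <- sum(scores[idx])
    out[idx] <- scores[idx] - (s - scores[idx]) / (length(idx) - 1L)
  }
  out
}

#' Rank tests over named variant sets with BH correction
#'
#' Runs [mwuTest()] per set on the chosen per-variant value and corrects
#' the tested sets with the Benjamini-Hochberg procedure. Sets whose
#' variants all fall in one group are skipped with a warning.
#'
#' @param sets named list of variant-id vectors.
#' @param values named numeric vector (names = variant ids).
#' @param labels named character vector of group labels (same names).
#' @param sided \code{"one"} or \code{"two"}.
#' @param positive target class label.
#' @return data.frame with one row per tested set: \code{set}, \code{U},
#'   \code{p}, \code{q}, \code{n_target}, \code{n_other}.
#' @export
variantSetTest <- function(sets, values, labels, sided = c("one", "two"),
                           positive = .defaultPositive(labels)) {
  sided <- match.arg(sided)
  unknown <- setdiff(unique(unlist(sets)), names(values))
  if (length(unknown))
    stop("sets reference unknown variant ids: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    lab <- labels[ids]
    if (length(unique(lab)) < 2L) {
      warning("set '", nm, "' has variants from only one group; skipped")
      return(NULL)
    }
    res <- mwuTest(values[ids[lab == positive]],
                   values[ids[lab != positive]], sided = sided)
    data.frame(set = nm, U = res$U, p = res$p,
               n_target = res$n_target, n_other = res$n_other,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable sets")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("set", "U", "p", "q", "n_target", "n_other")]
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param nTests number of tests (e.g. number of neighborhoods).
#' @return alpha / nTests.
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (nTests < 1L) stop("nTests must be >= 1")
  alpha / nTests
}

#' Per-neighborhood local-GC rank tests
#'
#' Runs [mwuTest()] on the per-variant values of each neighborhood;
#' neighborhoods whose variants fall in a single group are reported with
#' \code{NA} p-values rather than tested.
#'
#' @param neighborhoods list of \linkS4class{Neighborhood} objects (or of
#'   variant-id vectors), optionally named.
#' @param values named numeric per-variant values (GC counts or scores).
#' @param labels named character group labels.
#' @param sided \code{"one"} or \code{"two"}.
#' @param positive target class label.
#' @return data.frame with \code{neighborhood}, \code{U}, \code{p},
#'   \code{n_target}, \code{n_other}.
#' @export
neighborhoodGcTests <- function(neighborhoods, values, labels,
                                sided = "one",
                                positive = .defaultPositive(labels)) {
  ids <- lapply(neighborhoods, function(x)
    if (methods::is(x, "Neighborhood")) variantIds(x) else x)
  nms <- if (!is.null(names(neighborhoods))) names(neighborhoods)
         else vapply(neighborhoods, function(x)
           if (methods::is(x, "Neighborhood")) centerGene(x) else NA_character_, "")
  rows <- lapply(seq_along(ids), function(j) {
    lab <- labels[ids[[j]]]
    if (length(unique(lab)) < 2L)
      return(data.frame(neighborhood = nms[j], U = NA_real_, p = NA_real_,
                        n_target = sum(lab == positive),
                        n_other = sum(lab != positive),
                        stringsAsFactors = FALSE))
    res <- mwuTest(values[ids[[j]]][lab == positive],
                   values[ids[[j]]][lab != positive], sided = sided)
    data.frame(neighborhood = nms[j], U = res$U, p = res$p,
               n_target = res$n_target, n_other = res$n_other,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Swap proband/sibling labels within pairs
#'
#' Per family, with probability 1/2, all of that family's variants
#' exchange proband and sibling labels; per-family variant totals are
#' preserved by construction. Requires both roles to be represented in
#' every family.
#'
#' @param labels role label per variant (\code{"proband"}/\code{"sibling"}
#'   or any two labels).
#' @param families family id per variant.
#' @param seed optional integer seed.
#' @return list with \code{labels} (relabeled vector) and \code{swapped}
#'   (named logical per family).
#' @export
permutePairLabels <- function(labels, families, seed = NULL) {
  roles <- sort(unique(labels))
  if (length(roles) != 2L) stop("labels must contain exactly two roles")
  perFam <- tapply(labels, families, function(x) length(unique(x)))
  if (any(perFam < 2L))
    stop("family missing a role: ",
         paste(names(perFam)[perFam < 2L], collapse = ", "))
  fams <- sort(unique(families))
  swapped <- .withSeed(seed, stats::runif(length(fams)) < 0.5)
  names(swapped) <- fams
  out <- labels
  flip <- swapped[match(families, fams)]
  out[flip] <- ifelse(labels[flip] == roles[1L], roles[2L], roles[1L])
  list(labels = out, swapped = swapped)
}

#' Per-neighborhood p-values under within-pair label permutations
#'
#' Recomputes the neighborhood local-GC rank test on B datasets obtained by
#' randomly swapping the two role labels within each family, exactly as the
#' permutation FDR procedure requires. The rank of each neighborhood's
#' values is computed once and the B rank sums are obtained by a single
#' matrix product, so the cost is one small BLAS call per neighborhood.
#'
#' @param neighborhoods list of \linkS4class{Neighborhood} objects (or of
#'   variant-id vectors).
#' @param values named numeric vector of per-variant values (GC counts).
#' @param labels named character vector of role labels.
#' @param families named character vector of family ids.
#' @param B number of permutations (the framework default is 1000).
#' @param seed integer seed for the family swaps.
#' @param positive target class label.
#' @return numeric B x length(neighborhoods) matrix of one-sided p-values.
#' @export
permutationPvalues <- function(neighborhoods, values, labels, families,
                               B = 1000L, seed = NULL,
                               positive = .defaultPositive(labels)) {
  ids <- lapply(neighborhoods, function(x)
    if (methods::is(x, "Neighborhood")) variantIds(x) else x)
  fams <- sort(unique(families))
  swap <- .withSeed(seed,
    matrix(stats::runif(length(fams) * B) < 0.5, length(fams), B))
  rownames(swap) <- fams
  out <- matrix(NA_real_, B, length(ids))
  for (j in seq_along(ids)) {
    vid <- ids[[j]]
    vals <- values[vid]
    isT <- labels[vid] == positive
    fam <- families[vid]
    n <- length(vals)
    r <- rank(vals)
    ties <- table(vals)
    tieTerm <- sum(ties^3 - ties)
    flip <- swap[match(fam, fams), , drop = FALSE]   # n x B
    ind <- flip != isT                               # XOR: target after swap
    n1 <- colSums(ind)
    n2 <- n - n1
    R1 <- as.numeric(r %*% ind)
    U <- R1 - n1 * (n1 + 1) / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1))))
    mu <- n1 * n2 / 2
    p <- stats::pnorm((U - mu - 0.5) / pmax(sigma, .Machine$double.eps),
                      lower.tail = FALSE)
    p[sigma == 0 | n1 == 0L | n2 == 0L] <- 1
    out[, j] <- pmin(pmax(p, .Machine$double.xmin), 1)
  }
  out
}

#' Permutation-based FDR threshold over neighborhoods
#'
#' Candidate thresholds T are the observed p-values. At each T, discoveries
#' = |\{j : p_j < T\}| (strict), estimated false discoveries = the average
#' over permutations of |\{j : p^b_j < T\}|, and the estimated FDR is their
#' ratio. T is the largest observed p with estimated FDR at most
#' \code{targetFdr}; neighborhoods with p < T are flagged significant. When
#' no candidate satisfies the bound there are zero discoveries.
#'
#' @param observedP per-neighborhood observed p-values.
#' @param permutedP B x n matrix from [permutationPvalues()] (columns must
#'   align with \code{observedP}).
#' @param targetFdr target false discovery rate (default 0.05).
#' @return list with \code{threshold} (T, or NA when no discoveries),
#'   \code{n_discoveries}, \code{estimated_fdr}, \code{significant}
#'   (logical per neighborhood) and \code{B}.
#' @export
permutationFdr <- function(observedP, permutedP, targetFdr = 0.05) {
  if (ncol(permutedP) != length(observedP))
    stop("permutedP must have one column per neighborhood")
  B <- nrow(permutedP)
  permSorted <- sort(as.numeric(permutedP))
  obsSorted <- sort(as.numeric(observedP))
  candidates <- sort(unique(observedP), decreasing = TRUE)
  threshold <- NA_real_
  estFdr <- NA_real_
  for (T in candidates) {
    disc <- sum(obsSorted < T)  # strict
    if (disc == 0L) next
    fp <- .countBelow(permSorted, T) / B
    fdr <- fp / disc
    if (fdr <= targetFdr) {
      threshold <- T
      estFdr <- fdr
      break
    }
  }
  significant <- if (is.na(threshold)) rep(FALSE, length(observedP))
                 else observedP < threshold
  list(threshold = threshold, n_discoveries = sum(significant),
       estimated_fdr = estFdr, significant = significant, B = B)
}

# number of elements of sorted vector x strictly below t
.countBelow <- function(x, t) {
  findInterval(t, x, left.open = TRUE)
}
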