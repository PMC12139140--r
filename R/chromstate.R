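#' Annotate variant positions with chromatin-state labels
#'
#' Looks up the segmentation interval containing each variant's 1-based
#' position. Positions covered by no interval are labeled
#' \code{"unannotated"} with a warning (segmentations are genome-tiling,
#' so this indicates an incomplete file); positions covered by overlapping
#' intervals with conflicting labels are an error.
#'
#' @param variants data.frame with \code{chrom} and \code{pos}.
#' @param segmentation labeled \code{GRanges} from
#'   [readIntervalAnnotations()] with \code{labeled = TRUE}.
#' @return character vector of state labels per variant.
#' @export
annotateStates <- function(variants, segmentation) {
  if (is.null(segmentation$label)) stop("segmentation must carry a 'label' column")
  gr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  hits <- GenomicRanges::findOverlaps(gr, segmentation, ignore.strand = TRUE)
  lab <- rep(NA_character_, nrow(variants))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  for (i in unique(q)) {
    states <- unique(segmentation$label[s[q == i]])
    if (length(states) > 1L)
      stop("conflicting chromatin-state labels at ", variants$chrom[i], ":",
           variants$pos[i], " (", paste(states, collapse = ", "), ")")
    lab[i] <- states
  }
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " variant position(s) outside the segmentation; ",
            "labeled 'unannotated'")
    lab[is.na(lab)] <- "unannotated"
  }
  lab
}

#' Chromatin-state prediction of GC rank differences
#'
#' Quantifies how much of the between-group difference in local GC content
#' rank is predicted by chromatin-state annotations alone. GC counts are
#' converted to ranks with ties broken arbitrarily but reproducibly (seeded
#' random tie-break). Variants are randomly partitioned into
#' \code{nFolds} subsets; each variant's rank is predicted as the mean rank
#' of same-state variants in the other folds, using variants of both
#' groups. When a variant's state is unseen outside its fold, the fallback
#' is the mean rank of the training-fold variants (all states); the mean
#' rank of all variants globally is available via
#' \code{fallback = "global"}.
#'
#' percent_predicted = 100 * (mean prediction over target - mean
#' prediction over other) / (mean observed rank of target - mean observed
#' rank of other).
#'
#' @param gcCounts per-variant local GC counts.
#' @param labels group label per variant (two groups).
#' @param states chromatin-state label per variant.
#' @param nFolds number of random subsets (default 5).
#' @param seed integer seed (tie-break and fold partition).
#' @param fallback \code{"training"} (default) or \code{"global"}.
#' @param positive target group label.
#' @return list with \code{percent_predicted}, \code{per_state}
#'   (data.frame: state, contribution_pct, overlap_diff_pct, variants_pct),
#'   \code{predictions}, \code{ranks}, \code{fold}, \code{seed}. When the
#'   observed mean rank difference is exactly zero the result is undefined
#'   and reported as such via \code{percent_predicted = NA}.
#' @export
rankPrediction <- function(gcCounts, labels, states, nFolds = 5L, seed = 1L,
                           fallback = c("training", "global"),
                           positive = .defaultPositive(labels)) {
  fallback <- match.arg(fallback)
  n <- length(gcCounts)
  if (length(labels) != n || length(states) != n)
    stop("gcCounts, labels and states must be parallel")
  if (length(unique(labels)) != 2L) stop("exactly two groups required")
  res <- .withSeed(seed, {
    r <- rank(gcCounts, ties.method = "random")
    fold <- sample(rep_len(seq_len(nFolds), n))
    list(r = r, fold = fold)
  })
  r <- res$r; fold <- res$fold
  pred <- numeric(n)
  for (f in seq_len(nFolds)) {
    inFold <- fold == f
    trainR <- r[!inFold]
    trainS <- states[!inFold]
    stateMeans <- tapply(trainR, trainS, mean)
    fb <- if (fallback == "training") mean(trainR) else mean(r)
    p <- stateMeans[states[inFold]]
    p[is.na(p)] <- fb
    pred[inFold] <- p
  }
  isT <- labels == positive
  obsDiff <- mean(r[isT]) - mean(r[!isT])
  if (obsDiff == 0) {
    warning("observed mean rank difference is exactly zero; undefined result")
    pct <- NA_real_
  } else {
    pct <- 100 * (mean(pred[isT]) - mean(pred[!isT])) / obsDiff
  }
  perState <- stateContributions(pred, states, labels, r,
                                 positive = positive)
  list(percent_predicted = pct, per_state = perState, predictions = pred,
       ranks = r, fold = fold, seed = seed)
}

#' Per-state contributions to the predicted rank difference
#'
#' For each state s computes ((a_target,s - r) * f_target,s -
#' (a_other,s - r) * f_other,s), where a_.,s is the mean rank prediction of
#' the group's variants in state s, f_.,s the fraction of the group's
#' predictions in state s, and r the overall mean rank of all variants;
#' the quantity is divided by the observed mean rank difference and scaled
#' to percent. The decomposition is exact: contributions sum to the total
#' percent predicted. Individual values can be negative.
#'
#' @param predictions per-variant rank predictions.
#' @param states per-variant state labels.
#' @param labels per-variant group labels.
#' @param ranks observed (tie-broken) ranks.
#' @param positive target group label.
#' @return data.frame with \code{state}, \code{contribution_pct} (% of the
#'   observed mean rank difference predicted via this state),
#'   \code{overlap_diff_pct} (target minus other percent of variants in the
#'   state) and \code{variants_pct} (% of all variants in the state).
#' @export
stateContributions <- function(predictions, states, labels, ranks,
                               positive = .defaultPositive(labels)) {
  isT <- labels == positive
  rbar <- mean(ranks)
  obsDiff <- mean(ranks[isT]) - mean(ranks[!isT])
  allStates <- sort(unique(states))
  rows <- lapply(allStates, function(s) {
    inS <- states == s
    aT <- if (any(inS & isT)) mean(predictions[inS & isT]) else rbar
    aO <- if (any(inS & !isT)) mean(predictions[inS & !isT]) else rbar
    fT <- sum(inS & isT) / sum(isT)
    fO <- sum(inS & !isT) / sum(!isT)
    contrib <- (aT - rbar) * fT - (aO - rbar) * fO
    data.frame(state = s,
               contribution_pct = if (obsDiff == 0) NA_real_ else
                 100 * contrib / obsDiff,
               overlap_diff_pct = 100 * (fT - fO),
               variants_pct = 100 * sum(inS) / length(states),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
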