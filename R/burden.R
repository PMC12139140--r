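#' Paternal-age adjustment of per-sample de novo counts
#'
#' Ordinary least squares of total de novo count on paternal age; the
#' residual is shifted so its sample-wise mean equals the pre-adjustment
#' mean count, giving the adjusted total. Per-sample category counts (for
#' example coding or protein-truncating) are scaled by the sample's
#' adjusted/raw ratio; a sample with zero raw count gets ratio 1.
#'
#' @param samples data.frame with \code{sample_id}, \code{role},
#'   \code{paternal_age}, \code{total_count} and optionally further
#'   category count columns (any numeric column not among the above).
#' @return \code{samples} with \code{adjusted_total}, \code{ratio} and an
#'   \code{adjusted_<category>} column per category appended.
#' @export
paternalAgeAdjust <- function(samples) {
  req <- c("sample_id", "role", "paternal_age", "total_count")
  if (!all(req %in% names(samples)))
    stop("samples needs columns: ", paste(req, collapse = ", "))
  if (nrow(samples) < 2L) stop("need >= 2 samples for the regression")
  if (stats::var(samples$paternal_age) == 0)
    stop("paternal ages are all identical; skip the adjustment")
  if (any(samples$paternal_age <= 0)) stop("paternal_age must be positive")
  fit <- stats::lm(total_count ~ paternal_age, data = samples)
  adjusted <- stats::residuals(fit) + mean(samples$total_count)
  ratio <- ifelse(samples$total_count == 0, 1,
                  adjusted / samples$total_count)
  if (any(adjusted < 0))
    warning("negative adjusted total(s); downstream binomial tests will reject")
  samples$adjusted_total <- as.numeric(adjusted)
  samples$ratio <- as.numeric(ratio)
  cats <- setdiff(names(samples)[vapply(samples, is.numeric, TRUE)],
                  c("paternal_age", "total_count", "adjusted_total", "ratio"))
  for (cat in cats)
    samples[[paste0("adjusted_", cat)]] <- samples[[cat]] * samples$ratio
  samples
}

#' Two-sided binomial proband-vs-sibling burden test
#'
#' Tests whether the (possibly paternal-age-adjusted) proband count
#' differs from the sibling count, with successes = round(proband), trials
#' = round(proband + sibling) and null success probability \code{p0}
#' (default 0.5, the cohort design of one proband and one sibling per
#' family). Non-integer adjusted counts are rounded half-to-even before
#' the exact test.
#'
#' @param probandTotal,siblingTotal (adjusted) counts.
#' @param p0 null success probability.
#' @return list with \code{p}, \code{x}, \code{n}.
#' @export
binomialBurdenTest <- function(probandTotal, siblingTotal, p0 = 0.5) {
  if (probandTotal < 0 || siblingTotal < 0)
    stop("negative adjusted counts")
  x <- round(probandTotal)
  n <- round(probandTotal + siblingTotal)
  if (n == 0) stop("proband and sibling totals are both zero")
  p <- stats::binom.test(x, n, p = p0, alternative = "two.sided")$p.value
  list(p = p, x = x, n = n)
}
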