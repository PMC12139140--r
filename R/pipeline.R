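#' Default pipeline configuration
#'
#' Input paths plus the global parameters of the framework, every default
#' matching the reference setting: window length L = 201 bp, neighborhood
#' size M = 1000 variants, assignment radius 100 kbp, greedy-prune gap
#' ceiling(L/2) = 101 bp, optional promoter exclusion of 2 kbp, B = 1000
#' permutations at a target FDR of 0.05.
#'
#' @param genome,variants,tss,corr input file paths.
#' @param exclusions named character vector/list of BED paths.
#' @param L,M,max_dist,min_gap,promoter_exclusion,k,B,target_fdr,seed
#'   parameters (see description); \code{promoter_exclusion = 0} disables
#'   the promoter filter; \code{k = integer(0)} skips the k-mer tests.
#' @param orientation optional \code{"upstream"}/\code{"downstream"}.
#' @param proband_sex,sibling_sex,lane_match optional stratification.
#' @param permute run the permutation FDR correction (default TRUE).
#' @return a list of class \code{run_config}.
#' @export
runConfig <- function(genome, variants, tss, corr, exclusions = list(),
                      L = 201L, M = 1000L, max_dist = 100000L,
                      min_gap = as.integer(ceiling(L / 2)),
                      promoter_exclusion = 0L, orientation = NULL,
                      proband_sex = NULL, sibling_sex = NULL,
                      lane_match = NULL, k = integer(0), B = 1000L,
                      target_fdr = 0.05, permute = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [runConfig()] arguments.
#' @return a \code{run_config} list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  req <- c("genome", "variants", "tss", "corr")
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop("config lacks required field(s): ", paste(missing, collapse = ", "))
  do.call(runConfig, raw)
}

#' Run the full association pipeline
#'
#' Stages, in dependency order: read inputs, stratify, prepare variants
#' (windows, GC, TSS assignment, exclusion/orientation/promoter filters,
#' greedy pruning), build one neighborhood per matrix gene, per-
#' neighborhood one-sided local-GC rank tests, Bonferroni threshold and
#' (optionally) the within-pair permutation FDR. Each stage writes a TSV
#' under \code{outDir}; a run manifest records the config, input
#' checksums, per-stage row counts and the seed so a rerun is
#' byte-reproducible.
#'
#' @param config a [runConfig()] list (or path to a YAML config).
#' @param outDir output directory.
#' @return invisibly, a list with the prepared variants, neighborhoods,
#'   result table and manifest.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  genome <- readGenomeFasta(config$genome)
  variants <- readVariantTable(config$variants)
  tss <- readTssTable(config$tss)
  corr <- readCorrelationMatrix(config$corr)
  exclusions <- lapply(config$exclusions, readIntervalAnnotations)

  if (!is.null(config$proband_sex) || !is.null(config$sibling_sex) ||
      !is.null(config$lane_match))
    variants <- stratifyVariants(variants, probandSex = config$proband_sex,
                                 siblingSex = config$sibling_sex,
                                 laneMatch = config$lane_match)

  prep <- prepareVariants(variants, genome, tss, exclusions = exclusions,
                          L = config$L, maxDist = config$max_dist,
                          keepOrientation = config$orientation,
                          promoterExclusion = if (config$promoter_exclusion > 0)
                            config$promoter_exclusion else NULL,
                          minGap = config$min_gap)
  v <- prep$variants
  writeTsv(v[, setdiff(names(v), "window")],
           file.path(outDir, "prepared.tsv"))

  nbhds <- lapply(geneIds(corr), buildNeighborhood, corr = corr,
                  variants = v, M = config$M)
  names(nbhds) <- geneIds(corr)
  nbhdDf <- data.frame(center_gene = names(nbhds),
                       size = vapply(nbhds, function(x)
                         length(variantIds(x)), 0L),
                       undersized = vapply(nbhds, isUndersized, TRUE),
                       variant_ids = vapply(nbhds, function(x)
                         paste(variantIds(x), collapse = "|"), ""),
                       row.names = NULL, stringsAsFactors = FALSE)
  writeTsv(nbhdDf, file.path(outDir, "neighborhoods.tsv"))

  gcVals <- stats::setNames(v$gc_count, v$variant_id)
  labels <- stats::setNames(v$role, v$variant_id)
  families <- stats::setNames(v$family_id, v$variant_id)
  testable <- vapply(nbhds, function(nb) {
    lab <- labels[variantIds(nb)]
    length(lab) > 0L && length(unique(lab)) == 2L
  }, TRUE)
  results <- neighborhoodGcTests(nbhds[testable], gcVals, labels,
                                 sided = "one", positive = "proband")
  names(results)[names(results) == "neighborhood"] <- "center_gene"
  names(results)[names(results) == "n_target"] <- "n_proband"
  names(results)[names(results) == "n_other"] <- "n_sibling"
  bonf <- bonferroniThreshold(0.05, nrow(results))
  results$bonferroni_significant <- results$p <= bonf

  if (isTRUE(config$permute)) {
    permP <- permutationPvalues(nbhds[testable], gcVals, labels, families,
                                B = config$B, seed = config$seed)
    fdr <- permutationFdr(results$p, permP,
                          targetFdr = config$target_fdr)
    results$permutation_significant <- fdr$significant
  } else fdr <- NULL
  writeTsv(results, file.path(outDir, "gc_tests.tsv"))

  ## QQ-plot export: observed vs expected -log10 p
  pp <- sort(results$p)
  qq <- data.frame(expected = -log10(stats::ppoints(length(pp))),
                   observed = -log10(pp))
  writeTsv(qq, file.path(outDir, "qq.tsv"))

  inputs <- c(config$genome, config$variants, config$tss, config$corr,
              unlist(config$exclusions))
  manifest <- list(
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    seed = config$seed,
    stage_counts = list(variants_in = nrow(variants),
                        prepared = nrow(v),
                        drop_counts = as.list(prep$drop_counts),
                        neighborhoods = length(nbhds),
                        tested = nrow(results)),
    bonferroni_threshold = bonf,
    n_bonferroni_significant = sum(results$bonferroni_significant),
    n_permutation_significant = if (is.null(fdr)) NA else fdr$n_discoveries,
    permutation_threshold = if (is.null(fdr)) NA else fdr$threshold,
    version = as.character(utils::packageVersion("ensas")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(variants = v, neighborhoods = nbhds, results = results,
                 fdr = fdr, manifest = manifest))
}
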