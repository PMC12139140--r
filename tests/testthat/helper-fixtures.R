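# Small in-code fixture builders shared across the suite.

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# random genome as a DNAStringSet (no file round trip)
randomGenome <- function(lens, gc = 0.45, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  Biostrings::DNAStringSet(seqs)
}

toyVariants <- function(chrom, pos, family_id = "f1", role = "proband",
                        sex = "male", variant_id = NULL) {
  n <- length(pos)
  data.frame(
    variant_id = if (is.null(variant_id)) sprintf("v%03d", seq_len(n))
                 else variant_id,
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    family_id = rep_len(family_id, n), role = rep_len(role, n),
    sex = rep_len(sex, n), stringsAsFactors = FALSE)
}

toyCorr <- function(m, ids = paste0("g", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  CorrelationMatrix(m)
}

# a Neighborhood built directly from an id set (bypassing construction)
rawNeighborhood <- function(ids, M, center = "g1") {
  methods::new("Neighborhood", centerGene = center,
               variantIds = as.character(ids), genesUsed = center,
               M = as.integer(M), truncated = FALSE,
               undersized = length(ids) < M)
}

# exchangeable-label null fixture: disjoint neighborhoods, each with its
# own families contributing one proband and one sibling variant
nullNeighborhoodFixture <- function(nNbhd = 200, famPerNbhd = 50, L = 201,
                                    gcProb = 0.45, seed = 1) {
  set.seed(seed)
  nVar <- nNbhd * famPerNbhd * 2
  gc <- rbinom(nVar, L, gcProb)
  ids <- sprintf("v%06d", seq_len(nVar))
  fam <- sprintf("n%03d_f%03d",
                 rep(seq_len(nNbhd), each = famPerNbhd * 2),
                 rep(rep(seq_len(famPerNbhd), each = 2), nNbhd))
  role <- rep(c("proband", "sibling"), nVar / 2)
  names(gc) <- names(fam) <- names(role) <- ids
  nbhds <- split(ids, rep(seq_len(nNbhd), each = famPerNbhd * 2))
  list(gc = gc, labels = role, families = fam, neighborhoods = nbhds)
}
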