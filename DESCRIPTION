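Package: ensas
Title: Expression Neighborhood Sequence Association Study for De Novo Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether two groups of de novo noncoding variants (for example
    proband versus unaffected sibling) differ in local sequence composition
    within gene-expression-correlation neighborhoods. Provides readers for the
    formats involved (genome FASTA, variant tables, gene TSS tables, BED
    interval annotations, square correlation matrices), variant preparation
    (window extraction, local GC content, k-mer counting, nearest-TSS
    assignment with strand-aware upstream/downstream orientation, exclusion
    filters, greedy pruning), fixed-size expression-neighborhood construction
    and clustering, rank and multinomial Naive Bayes association tests with
    Bonferroni and within-pair permutation FDR corrections, chromatin-state
    rank-difference decomposition, paternal-age-adjusted burden tests, power
    simulations over chromatin-state segmentations, and a synthetic-fixture
    generator so the whole pipeline is exercisable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association.R'
    'burden.R'
    'chromstate.R'
    'ensas-package.R'
    'fixture.R'
    'io.R'
    'neighborhoods.R'
    'pipeline.R'
    'simulate.R'
    'variant-prep.R'
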