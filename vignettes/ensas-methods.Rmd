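---
title: "Expression-neighborhood sequence association: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-neighborhood sequence association: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensas)
```

## The problem

Family-based whole-genome sequencing yields de novo single-nucleotide
variants for an affected child (proband) and an unaffected sibling in each
family. A recurring question is whether proband variants differ from
sibling variants in their local sequence context — and if so, near which
genes. This package tests that question on *expression neighborhoods*:
variant sets anchored at a center gene and filled with the variants
assigned to the genes most correlated with it in a gene–gene expression
correlation matrix. Working at the neighborhood level covers expression
space systematically and holds the variant-set size fixed, which removes
set size as a confounder between tests.

Two sequence readouts are tested per neighborhood:

1. **Local GC content** — the number of G or C bases in the L-bp window
   centered on the variant (L = 201 by default: 100 bp of flank per side).
   A one-sided Mann–Whitney U test asks whether the target group (probands
   by default) has higher values.
2. **k-mer composition** — the overlapping k-mer counts of the same
   window feed a two-class multinomial Naive Bayes classifier with uniform
   class priors. Variants are split into evenly sized training and testing
   folds; the classifier is trained on one fold and the posterior
   probability of the target class is computed for each test-fold variant.
   The same one-sided rank test is then applied to the scores, and — for
   comparability — to the test fold's GC values.

## Variant preparation

Variants are assigned to the gene with the nearest *outermost* TSS (the
5'-most transcribed position in gene orientation) within 100 kbp. A
variant is **upstream** when its coordinate is less than the TSS of a
positive-strand gene, or greater than the TSS of a negative-strand gene;
all other assigned variants, including a variant exactly at the TSS, are
downstream (the upstream rule is a strict inequality, so the boundary
falls to the complement). Exclusion filters (coding intervals, canonical
splice sites, repeats — whatever BED inputs the caller supplies) run
before the distance/orientation filters, and an optional promoter filter
drops variants strictly less than 2 kbp upstream of their assigned TSS;
each filter reports an audit count so the cascade is reconstructible.
Finally, variants closer than ceiling(L/2) = 101 bp are greedily pruned
per chromosome, keeping the smaller coordinate of each close pair. This
guarantees non-overlapping windows, so no sequence content is counted
twice within a neighborhood.

Degenerate inputs: windows that would run off a chromosome end cannot be
length-L and are dropped with a logged count rather than padded (this
cannot happen on real autosomes with 100-bp flanks but can on toy
fixtures). N bases count as non-GC, and any k-mer containing a non-ACGT
character is skipped entirely — both choices keep window extraction
length-stable while leaving the interpretation of ambiguous sequence to
the counting layer.

## Neighborhood construction and ties

The neighborhood of center gene *g* holds the top M variants (M = 1000 by
default, matching the scale of typical tissue-specific gene sets) drawn by
visiting genes in order of decreasing correlation with *g*, center first.
Two tie situations are made deterministic deliberately: correlation ties
are broken by ascending gene id, and when a gene's variants would overshoot
M, its variants are added in ascending (chrom, pos) order until exactly M.
Both tie-breaks are arbitrary in principle; fixing them makes every
neighborhood, and therefore every downstream p-value, reproducible from
the inputs alone. The distance between two neighborhoods is M minus their
shared variant count — the Manhattan distance between binary membership
vectors. Clustering of top neighborhoods uses density clustering with
minimum cluster size 1 at radius M/2, which reduces exactly to connected
components of the distance-below-eps graph; because chaining can violate
the all-pairs-within-eps reading of a cluster, that property is asserted
after clustering and violations are reported in a warning instead of being
silently accepted or silently enforced.

## Rank test and multiple testing

The U statistic is computed by midrank assignment, and p-values use the
normal approximation with tie correction and continuity correction — the
convention of the standard scientific stacks, appropriate at neighborhood
sizes of hundreds to a thousand. Exact enumeration appears only in tests,
as an oracle.

Two corrections are offered. The Bonferroni threshold is 0.05/n over the
n neighborhoods tested. The permutation alternative swaps the
proband/sibling labels within each family with probability 1/2 per
permutation — the exchangeability that the paired design licenses — and
reruns the identical per-neighborhood test on each of B relabeled datasets
(B = 1000 by default). For a candidate threshold T (drawn from the
observed p-values), discoveries are the neighborhoods with p strictly
below T, the estimated false discoveries are the average number of
permuted p-values strictly below T, and T is chosen as the largest
candidate whose estimated FDR is at most the target (0.05). All
inequalities are strict, matching the estimator's definition. The
permuted p-value matrix is computed by a batched rank-sum path
(`permutationPvalues`): ranks are computed once per neighborhood and the B
rank sums come from one matrix product, which is what makes
B × n-neighborhood calibration studies affordable.

Laplace smoothing for the classifier defaults to alpha = 1 (the universal
multinomial default; exposed as an argument), and the train/test split is
stratified by class so both folds always contain both classes —
unstratified splitting is available behind a flag but can error on
single-class folds, which is the correct failure mode rather than a
silent degenerate test.

## Chromatin-state decomposition

For a chosen neighborhood, each variant gets the label of the
segmentation interval containing its position. GC counts are converted to
ranks with ties broken by a seeded random shuffle (the seed is part of
the result). Variants are partitioned into five random folds; each
variant's rank is predicted as the mean rank of same-state variants
outside its fold, pooling both groups. When a state is unseen outside the
fold, the fallback is the mean rank of the training-fold variants — the
global-mean variant is available behind a flag, but the training-fold
version avoids leaking the held-out variant's own rank into its
prediction. The percent of the group difference predicted is
100 × (mean prediction of target − mean prediction of other) / (observed
mean rank difference); an observed difference of exactly zero makes the
ratio undefined and is reported as NA with a warning. The per-state
contribution ((a_target,s − r)·f_target,s − (a_other,s − r)·f_other,s),
scaled the same way, decomposes the total *exactly* — the identity
Σ_s (a·f) = mean prediction is algebraic — and the package asserts the
conservation in its tests to 1e-6. Unannotated variants form their own
pseudo-state rather than being dropped, which preserves that identity.

## Simulations and the synthetic fixture

Two generators make the whole pipeline testable without restricted data.

`simulateSegmentedGenome` builds a small genome with a genome-tiling
chromatin-state segmentation: promoter-like clusters (TssFlnkU, TssA,
TssFlnk, TssFlnkD, then Tx and EnhBiv) embedded in a quiescent background,
with occasional assembly gaps written as N runs. In `"gc"` mode the
TSS-associated states are GC-enriched; in `"cpg"` mode every state has
the same uniform base composition but TSS states come from a
doubly-stochastic first-order Markov chain that boosts CpG dinucleotides —
GC content is uninformative there by construction while 2-mers and longer
carry signal. The `"cpg"` regime exists to demonstrate that the k-mer
classifier can detect composition differences invisible to GC content.

`simulateStateVariants` draws X% of target-group positions uniformly from
the TSS-state intervals and everything else uniformly genome-wide
excluding gaps, then prunes to a 100-bp minimum gap. Draws use exact
cumulative-length inversion over the (gap-complemented) interval union.
Pruning losses are refilled from the same pools and re-pruned, up to 100
attempts, so group sizes stay exact; at toy genome sizes a full-dataset
redraw would essentially never produce a collision-free draw, so refilling
is the feasible route to the same end. The power study
(`runPowerStudy`) reports, per X and method, the fraction of datasets
whose median test-fold p-value over repeated splits falls below 0.05. The
reference grid is X ∈ {10, 20, 50, 80, 100} with 500 variants per group,
50 datasets and 50 splits; the package's own acceptance checks run a
scaled-down grid (X ∈ {0, 20, 50, 80, 100}, 200 per group, 20 datasets,
20 splits, k ∈ {1, 2}) — sizes chosen so the whole calibration suite runs
in minutes on one core while keeping the binomial noise on each power
estimate below ±0.1.

`generateFixture` writes a complete input bundle: genome FASTA with
promoter-like high-GC islands (so the bundled segmentation correlates
with the GC landscape), a TSS table with both strands, a block-structured
correlation matrix (within-block correlations 0.6–0.9, between ≈ 0),
paired proband/sibling variants with sex drawn at the cohort-scale rates
(87% male probands, 47% male siblings, ~19 variants per child), lane
metadata, exclusion BEDs, and an optional planted effect: proband
variants assigned to one gene block sit in window-sized patches whose
per-base GC probability is raised by delta/L, so the expected window GC
count shifts by delta. The manifest records the seed, all realized
parameters, and the realized shift with its Monte-Carlo standard error.
Defaults (4 chromosomes × 250 kbp, 60 genes in 3 blocks, 50 families)
are a deliberate desk-scale compromise: large enough that neighborhoods,
permutations and the planted-signal recovery behave like the full-scale
analysis, small enough to regenerate from code in seconds.

What the fixtures do *not* emulate: mutational signatures, repeat
structure, linkage between neighboring variants, realistic correlation
spectra (real matrices are not block-diagonal), or sequencing artifacts.
Passing the calibration and recovery suites therefore shows the
machinery is correct and calibrated under exchangeability and detects
planted composition shifts of the stated size — it does not certify
power or FDR behavior on real cohort data.

## Burden tests

Per-sample total de novo counts are adjusted for paternal age by OLS; the
residual is shifted to restore the pre-adjustment mean, and category
counts scale by each sample's adjusted/raw ratio (ratio 1 when the raw
total is zero). Proband-vs-sibling category totals are compared with an
exact two-sided binomial test at null probability 0.5 — the cohort design
of one proband and one sibling per family forces 0.5, but the probability
is an argument for unbalanced designs. Adjusted totals are rounded
half-to-even before the exact test; at least two samples with non-constant
ages are required for the regression (two exactly-fitting points are the
smallest meaningful case).

## Known limitations

* The Mann–Whitney p-value is asymptotic; below roughly 10 variants per
  group the approximation is loose (the package still computes it, and
  the tests document the error against exact enumeration at tiny n).
* Neighborhoods overlap heavily by construction, so Bonferroni over all
  centers is conservative; the permutation FDR is the calibrated
  alternative but costs B full re-analyses.
* The density clustering honors the strict-radius graph, not complete
  linkage; violations are only reported.
* The thin VCF adapter reads chromosome and position only; rich VCF
  workflows should convert to the flat variant table first.
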