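# ensas

Tests whether two groups of de novo noncoding variants — canonically the
affected proband versus the unaffected sibling of each family in a paired
whole-genome-sequencing cohort — differ in local sequence composition
within **gene-expression neighborhoods**, and provides the supporting
machinery around that test: variant preparation, neighborhood
construction and clustering, permutation-based FDR control,
chromatin-state decomposition of the signal, burden tests, power
simulations, and a synthetic-fixture generator so everything is
exercisable without access-controlled cohort data.

## The method

For a center gene *g*, the neighborhood *N(g)* is the set of the top
*M* variants (default 1000) assigned to the genes most correlated with
*g* in a gene–gene expression correlation matrix, visited center-first in
decreasing correlation order. Each variant carries the *L*-bp sequence
window centered on it (default *L* = 201). Per neighborhood, two tests
compare proband against sibling variants:

* **Local GC content** — a one-sided Mann–Whitney *U* test on the number
  of G/C bases per window (*U* by midrank assignment; tie-corrected
  normal approximation with continuity correction).
* **k-mer composition** — windows are split into evenly sized training
  and testing folds; a multinomial Naive Bayes classifier with uniform
  class priors and Laplace smoothing (θ<sub>c,w</sub> = (N<sub>c,w</sub> + α)/(N<sub>c</sub> + α·4<sup>k</sup>))
  is trained on the k-mer counts of one fold, the posterior probability
  of the target class is computed for the other, and the same one-sided
  rank test is applied to the scores.

Multiple testing over the *n* neighborhoods is controlled either by
Bonferroni (0.05/*n*) or by a permutation procedure that swaps
proband/sibling labels within each family and chooses the largest
p-value threshold *T* with estimated FDR
(Σ<sub>b</sub>|{j: p<sub>j</sub><sup>b</sup> < T}|/B) / |{j: p<sub>j</sub> < T}| ≤ 0.05.
A chromatin-state module quantifies the percent of the observed mean GC
rank difference predicted by segmentation labels alone and decomposes it
exactly by state.

## Worked example

Generate a synthetic input bundle with a GC shift of +15 expected G/C
bases per 201-bp window planted into the proband variants of one gene
block, then run the full pipeline:

```r
library(ensas)

fx  <- file.path(tempdir(), "fixture")
man <- generateFixture(fixtureConfig(delta = 15, seed = 8), fx)

cfg <- runConfig(genome     = file.path(fx, "genome.fa"),
                 variants   = file.path(fx, "variants.tsv"),
                 tss        = file.path(fx, "tss.tsv"),
                 corr       = file.path(fx, "corr.tsv"),
                 exclusions = list(coding = file.path(fx, "coding.bed"),
                                   css    = file.path(fx, "css.bed")),
                 M = 200, B = 200, seed = 2)
res <- runPipeline(cfg, file.path(tempdir(), "out"))
head(res$results[order(res$results$p), ], 5)
```

```
 center_gene            p n_proband n_sibling bonferroni_significant permutation_significant
        g034 1.373859e-17        90       110                   TRUE                    TRUE
        g040 1.486803e-16        93       107                   TRUE                    TRUE
        g055 1.048422e-15        85       115                   TRUE                    TRUE
        g022 5.304132e-15        88       112                   TRUE                    TRUE
        g004 1.404146e-14        85       115                   TRUE                    TRUE
```

Every top neighborhood is centered on a gene of the planted block
(`g001, g004, g007, ...` — the block members are listed in the fixture's
`manifest.json`, which also reports the realized shift, here 15.09). The
run's own `manifest.json` records the Bonferroni threshold
(0.05/60 ≈ 8.3e-4), the permutation threshold and 19 permutation-significant
neighborhoods, input checksums, per-stage drop counts and the seed; rerunning
from the same config reproduces every output byte-identically.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ensas.R`:

```sh
Rscript inst/scripts/ensas.R fixture --seed 8 --delta 15 --out fixture/
Rscript inst/scripts/ensas.R run --config run.yaml --out results/
```

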