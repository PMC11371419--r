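# ecoconv

Convergence genomics of repeatedly evolved ecomorphs: aggregation of
branch-site positive-selection screens, relative-evolutionary-rate (RER)
trait association, protein-convergence (ωc) filtering, gene-reuse vs
divergence-time regression, and gene-set enrichment with randomization
nulls — as a tested, reusable R package plus a numbered analysis workflow.

## The problem

Bat ecomorphs (gleaning, trawling, and aerial-hawking *Myotis*-type
foragers) evolved the same phenotypes independently in different
biogeographic regions. Given genome-wide screen outputs — per-gene
per-branch selection p-values, per-gene branch-length matrices, ωc
branch-pair convergence records, and a time-calibrated phylogeny — the
question is whether repeated phenotypes re-use the *same genes* or
*different genes with the same functions*. The package implements the
downstream statistics:

- within-gene Benjamini–Hochberg over each gene's tested branches; calls
  with `q ≤ α` populate a gene × branch selection matrix in which
  "untested" stays distinct from "not selected";
- per-ecomorph gene sets (selected in ≥ 1 species), Venn partitions, and
  exclusive fractions;
- RERs as standardized residuals of `√(gene branch length)` on
  `√(master branch length)` (binned inverse-variance weights), associated
  with the 0/1 ecomorph indicator by Kendall's τ_b with an exact rank-sum
  null for the binary case;
- gene reuse for each same-ecomorph species pair: shared selected genes
  `s_ab`, normalized by the maximum observed count
  (`s_ab / max_cd s_cd`, so the top pair scores exactly 1.0), regressed
  on node age `(d(a→MRCA) + d(b→MRCA))/2`;
- one-sided hypergeometric enrichment `P(X ≥ k)` for study hits `k` of
  `K` annotated genes in an `N`-gene universe with study size `n`, BH
  q-values, GO-depth filtering, matched-size randomization nulls, and
  per-species robustness.

A synthetic-data module generates the whole study (Yule chronogram with
scattered ecomorph labels, planted convergent genes, age-decaying pair
sharing, planted enriched terms), so every stage is testable against
ground truth without any external data.

## Worked example

The `analysis/` scripts run the full study on a simulated 30-taxon,
2000-gene screen (seed 1):

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_selection_screen.R
Rscript analysis/03_rate_association.R
Rscript analysis/04_convergence_overlap.R
Rscript analysis/05_gene_reuse.R
Rscript analysis/06_enrichment.R
```

Stage 2 prints the screen aggregation:

```
trawler         210 genes selected in >= 1 species
gleaner         189 genes selected in >= 1 species
aerial_hawker   193 genes selected in >= 1 species
venn_partition (trawler / gleaner / aerial_hawker)
a_only b_only c_only     ab     ac     bc    abc
   175    149    160     20     13     18      2
exclusive fractions: trawler = 0.833, gleaner = 0.788, aerial_hawker = 0.829
```

Roughly 80% of each ecomorph's selected genes are private to that
ecomorph — repeated evolution mostly touched different genes. Stage 5
measures gene reuse against divergence time:

```
70 same-ecomorph pairs; max shared count 10 (that pair = 1.0)
All selected genes:
OLS fit (n = 70): slope = -0.01339, intercept = 0.7881
  R^2 = 0.3558, F(1,68) = 37.55, P = 5.073e-08
```

The fitted slope is negative: under the simulated age-decaying retention,
recently diverged pairs share more selected genes, and the regression
recovers that sign. Stage 6 recovers the planted annotation term
(`T001 [planted]`, q < 0.01 in two of three ecomorphs) and shows the
randomization null separating it from same-sized random draws.

Programmatic use mirrors the scripts:

```r
library(ecoconv)
s <- run_pipeline(list(seed = 1, simulate = list(), output_dir = "run1"))
str(s$exclusive_fractions)
```

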