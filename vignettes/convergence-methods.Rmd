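---
title: "Measuring convergent gene selection and gene reuse across ecomorphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring convergent gene selection and gene reuse across ecomorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoconv)
```

## The question and the design

When the same phenotype evolves repeatedly — here, three bat foraging
ecomorphs (gleaners, trawlers, aerial hawkers) that each arose several
times in different biogeographic regions — does evolution re-use the same
genes, or different genes with the same functions? `ecoconv` implements
the full downstream analysis that answers this from genome-wide screen
outputs:

1. **Selection-screen aggregation.** Per-gene, per-branch p-values from a
   branch-site positive-selection test are corrected by Benjamini–Hochberg
   *within each gene* (each gene's branches form their own family), and a
   gene × branch selection matrix is built. A branch absent from a gene's
   alignment stays `NA` throughout: untested is never evidence of no
   selection.
2. **Group gene sets.** For each ecomorph, the union of genes selected on
   the terminal branches of its species ("at least one species" rule), the
   three-set Venn partition, and each set's exclusive fraction.
3. **Relative evolutionary rates (RER).** Residual per-branch rates after
   regressing transformed gene branch lengths on genome-average branch
   lengths, associated with a 0/1 ecomorph indicator by Kendall's tau-b.
4. **Protein convergence.** Filtering of externally computed ωc branch-pair
   records (ωc ≥ 3, `any2spe` mode, foreground-touching pairs) and the
   three-way overlap of all evidence types.
5. **Gene reuse.** Pairwise shared-selected-gene counts among
   same-ecomorph species pairs, normalized by the maximum observed count,
   regressed on pair node age.
6. **Enrichment.** Hypergeometric gene-set tests with BH q-values, GO-depth
   filtering, a matched-size randomization null, and per-species
   robustness runs.

Everything runs end to end on synthetic data with the statistical
structure the design assumes, so every stage has a ground-truth test
surface.

## Branch identity

Branches are identified by their descendant tip set, encoded as the sorted
tip labels joined with `"|"`. This is the only identity that survives
per-gene pruning: a screen spanning thousands of gene trees, each missing
a different subset of taxa, can still attribute every tested branch to the
same biological lineage. After `prune_to_taxa()`, a surviving branch's
identity equals its original tip set intersected with the kept taxa.

Node age for a species pair is the mean of the two tip-to-MRCA path
lengths — on an ultrametric chronogram, simply the MRCA depth below the
present. Ultrametricity is *reported*, not enforced
(`is_ultrametric_tree()`, absolute tolerance 1e-6 My), because penalized-
likelihood chronograms can deviate slightly.

## The RER construction and its p-values

The RER core is a deliberately simplified, self-contained reimplementation
of the published approach (data transformation plus weighted regression
with a heteroscedasticity correction). Defaults:

* transform: `sqrt` (variance-stabilizing for branch lengths); `log1p`
  available;
* weighting: residual variance estimated in 10 master-length bins from an
  unweighted first pass, second pass weighted by inverse bin variance;
* per-gene standardization of residuals to unit scale;
* `min_n = 10` branches per scored gene, `min_genes = 5` genes per
  master branch.

Phylogenetic covariance of residuals beyond the master-tree regression is
**not** modeled; that is a stated limitation, and p-values should be read
as measures of rank association, not as phylogenetically corrected tests.

For the trait association, the foreground is the set of terminal branches
of one ecomorph's species: phenotypes are observable only in extant
species. Kendall's tau-b handles the massive ties in a 0/1 indicator. The
p-value policy picks the sharpest valid null:

* `n ≤ 9`: exact permutation null by full enumeration (correct under any
  ties);
* one binary variable against tie-free rates: the concordance statistic
  `S` is a linear map of Mann–Whitney `U` (`S = 2U − m₁m₀`), so the exact
  rank-sum null is used at any `n`;
* otherwise: normal approximation with tie-corrected variance and
  continuity correction.

The middle case matters in practice. With ~7 foreground branches out of
58, the normal tail is visibly conservative: under the package's own null
simulation the fraction of genes at p ≤ 0.01 came out near 0.004 with the
normal approximation, below the binomial 99% band around the nominal rate,
while the exact rank-sum null sits inside it. Since the binary-trait scan
is exactly the situation the association test exists for, the exact null
is the default there.

## Gene reuse and its normalization

For each same-ecomorph pair, the shared count is the number of genes
called selected on both terminal branches, counting only genes tested in
both species. Proportions are counts divided by the *maximum observed
shared count* (that pair scores exactly 1.0). Normalizing by the total
number of screened genes is deliberately avoided: with a five-digit
denominator all proportions collapse toward zero and differences are
uninterpretable without a further log transform. Raw-count regression is
available as a sensitivity variant; it has identical R² by construction.

Node ages come from the full, unpruned chronogram. Cross-ecomorph pairs
are excluded by default (reuse is defined within a repeatedly evolved
phenotype); outgroup pairs can be added for contrast. Whether genes
untested in one species of a pair should count was an open choice; the
package excludes them from that pair's universe and documents the rule.

## Enrichment decisions

The web enrichment service used in this kind of study is replaced by the
standard one-sided hypergeometric test with BH correction; comparisons are
at the level of which terms pass q < 0.05, not exact q values. The default
background is the screened/annotatable universe (conditioning on
testability), not the whole genome. With a term graph, a gene annotated to
a term counts for all ancestors; flat GMT mode skips propagation. The
depth filter keeps terms within `max_depth = 5` is_a steps of the root
term. The randomization null redraws gene sets of the observed size
uniformly from the background, with empirical p
`(1 + #{null ≤ observed})/(1 + draws)` (add-one correction, 1000 draws by
default, seed mandatory).

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions; the defaults are the
documented conditions of every calibration and recovery analysis:

| parameter | default | meaning |
|---|---|---|
| `n_taxa`, `n_outgroup` | 30, 8 | 22 focal species (8/5/9 across the three ecomorphs, mirroring a real 30-genome design) plus outgroups |
| `root_age` | 50 My | chronogram scale |
| `n_genes` | 2000 | desk-scale stand-in for a ~16k-gene screen |
| `pi0` | 0.01 | baseline per-branch selection probability; puts per-group union sets at a few percent of the screen, as observed in real screens |
| `rho_conv`, `p_fg` | 0.05, 0.6 | fraction of convergent genes per ecomorph and their foreground selection probability |
| `lambda_age` | 0.03 /My | loss rate of the shared latent gene pool |
| `mu_fg`, `sigma` | 2, 0.2 | foreground rate multiplier and lognormal length noise |
| `missing_rate` | 0.05 | absent gene × branch cells |

Trees are pure-birth (Yule), rescaled to the root age; only
ultrametricity and clade structure matter downstream. Ecomorph labels are
assigned cyclically along the ladderized tip order, which guarantees each
phenotype is scattered over several non-sister clades — the
repeated-evolution structure. Reuse decay uses a shared latent gene pool
per ecomorph: a convergent gene is present at the root and lost along each
branch at rate `lambda_age`, so two species at node age *t* both retain it
with probability `exp(−λ(T + t))` — sharing decays with divergence time,
and `λ = 0` switches the decay off. Selected cells draw p-values from
Beta(0.05, 10) truncated below `alpha / n_branches`, which guarantees
planted positives survive the within-gene BH step; background cells draw
uniform p-values.

The generator does **not** simulate sequences, codon alignments, the
branch-site likelihood itself, or the ωc computation; their outputs are
emulated at the statistics level. Passing tests therefore show that the
*analysis* is correct and calibrated under the assumed statistical
structure — not that the upstream tools would behave on real alignments.

## Numerical choices and degenerate inputs

* BH within gene via the standard step-up; `alpha = 0` is allowed and
  yields an all-empty screen that propagates cleanly (regressions then
  report an error entry rather than crashing).
* OLS fits report slope 0, R² 0, p 1 when the response is constant; a
  constant predictor is an error.
* RER residual standardization skips genes whose fit is exact to < 1e-9
  (zeros are kept rather than amplifying float noise).
* ωc filtering is inclusive at the threshold (≥ 3 keeps 3.0 exactly).
* `filter_omega_c` requires ≥ 1 branch of the pair in the foreground by
  default; `require_both = TRUE` is available since the stricter reading
  is also defensible.
* Zero-length terminal branches are allowed with a warning (they create
  node-age ties).
* All simulation randomness derives from the config seed; the pipeline is
  bit-reproducible for a fixed config.

## Problem sizes used in the shipped analyses

The analysis scripts and acceptance checks run at 30 taxa × 2000 genes
(simulation-based calibration at 2000 genes; recovery analyses at 800
genes × 4 multiplier levels; reuse sign-recovery over 50–100 seeded
replicates; randomization uniformity over 1000 repeats of 199 draws).
These sizes give stable Monte-Carlo estimates for every check while
keeping a full run in minutes on one core.

## A small worked run

```{r pipeline, eval = TRUE}
s <- run_pipeline(list(seed = 11,
                       simulate = list(n_taxa = 12, n_outgroup = 3,
                                       n_genes = 300),
                       output_dir = tempfile("demo")))
unlist(s$group_set_sizes)
round(unlist(s$exclusive_fractions), 2)
```

## Known limitations

* The RER stand-in ignores residual phylogenetic covariance; genes on
  closely related branches are not independent draws.
* The exact rank-sum null assumes tie-free rates; heavily tied rate
  matrices fall back to the (conservative) normal approximation.
* The reuse regression is ordinary least squares over pairs, which share
  species; pair non-independence is not modeled, matching the original
  analysis design rather than improving on it.
* Headline quantities from any real 30-genome screen (specific R² values,
  gene counts) are functions of the real data and are not reproduced by
  the synthetic conditions; the package reproduces the *procedures* and
  verifies their statistical behavior.
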