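---
title: "Methods: TF-type conservation under genome reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-type conservation under genome reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulogr)
```

# The question and the model

Bacteria that become host-restricted lose genes irreversibly, and
regulatory genes are lost faster than the genes they regulate. `regulogr`
quantifies whether the three effective regulatory types of transcription
factor — activator, repressor, dual — are lost at different rates, using a
reference transcriptional regulatory network (TRN) as the comparative
template. This vignette documents the statistical machinery, the
parameters that matter, the synthetic data model, and the package's
numerical conventions.

## Regulog reconstruction and its assumptions

A regulatory interaction TF → TG in the reference is inferred in a target
genome when both endpoints have orthologs there (`reconstruct_trn()`).
Orthology is operational: bidirectional best hits (`best_hit_per_query()`,
`bidirectional_best_hits()`) over BLAST tabular hit tables, accepted when
all three of

* e-value `< 1e-6`,
* percent identity `> 30`,
* alignment length `> 0.60 ×` **each** protein's length

hold strictly. The coverage rule is enforced against both lengths: the
criterion speaks of a fraction of the individual proteins, and the two-sided
reading is the conservative one. Best hits are chosen by lowest e-value
with ties broken by highest bitscore, then lexicographic subject id; the
tie-break is not biologically meaningful, it only makes runs reproducible.
Best hits are selected *before* thresholds are applied, then filtered —
so a sub-threshold alignment that happens to outrank the genuine hit
suppresses the pair rather than silently passing.

Two assumptions are inherited from the approach, not improved on: TFs keep
their regulatory type across genomes, and conserved sequences imply
conserved interactions. Both weaken with evolutionary distance; the method
is intended for closely related genomes.

## Conservation statistics

For a reference coding `N` TFs with `K` of a focal type, a genome
conserving `n` orthologous TFs of which `k` are of that type is tested
one-sided — H0: the genome's type fraction is at most the reference's —
with the hypergeometric upper tail `P(X >= k)` (`hypergeom_upper_tail()`,
computed through the log-space distribution function so reference sets of
thousands of genes are no problem). The tail *includes* the observed `k`,
matching the "greater" alternative for a discrete statistic. `n` counts
every conserved TF, including unclassified ones, and the same `n` is the
denominator of the reported fractions: the sampling model draws `n` TFs
without replacement from all `N`, so restricting the denominator to
classified TFs would break the correspondence between fraction and test.
Sigma factors are regulators but never TFs here; they are carried through
reconstruction for the globality metric and excluded from all TF-type
statistics.

Genomes with `n = 0` cannot be tested; they are flagged `untestable` and
dropped from the per-type Fisher combination
(`fisher_combine()`, `X = -2 * sum(log(p))` against chi-square with `2m`
df) rather than imputed. No further multiple-testing correction is applied
beyond the combination.

## The globality metric

```
G(x) = 1/4 * ( TFR/(N_TF + N_SF - 1) + GR/N_G + SF/N_SF + CR/(N_TF - 1) )
```

Each of the four connectivity components is normalized by its maximum, so
`G` lies in `[0, 1]` and is monotone in every component. `TFR` counts
regulator-kind targets (TFs *and* sigma factors — that is why its
denominator spans both); auto-regulation is excluded from `TFR` and `CR`
(the `-1` denominators exclude self). In degenerate networks (no sigma
factors, or a single TF) the affected term contributes 0 with a warning
rather than dividing by zero. Scores are reported at full precision;
display rounding is to 4 decimals and preserves the full-precision
ordering. The `is_global` flag marks the top decile of `G` in the
reference network — an operational cutoff, configurable
(`global_quantile`), and replaceable by curated annotation where one
exists.

## Independent contrasts and through-origin statistics

`compute_contrasts()` implements the standard recursion: post-order, at a
node with children `(x_a, v_a)`, `(x_b, v_b)` the raw contrast is
`x_a - x_b` with variance `v_a + v_b`, the node receives the
precision-weighted ancestral value, and its branch is augmented by
`v_a v_b / (v_a + v_b)`. Ancestral values and augmented lengths are kept
as attributes for inspection. Requirements and conventions:

* trees must be rooted, bifurcating (`resolve_polytomies()` expands
  multifurcations into zero-length caterpillars, seed-deterministic) and
  carry branch lengths in expected-variance units;
* a node whose combined variance is exactly zero gets `epsilon = 1e-8` on
  both branches, only then, with a warning;
* contrasts have arbitrary sign, so bivariate statistics run through the
  origin after positivizing the X contrasts (`positivize()` flips pairs
  jointly); degrees of freedom are `contrasts - 1`;
* no branch-length transformation is applied automatically.

Under Brownian-motion evolution the standardized contrasts are iid with
variance equal to the Brownian rate; the test suite verifies this
calibration on simulated traits, and verifies that on a star phylogeny the
through-origin contrast correlation collapses to the ordinary Pearson
correlation of the leaf values.

Nine variables enter the contrast analyses against genome size: size
itself, the three per-type conserved-TF counts, the three per-type
fractions, and the global-regulator and NAP fractions. Fraction traits are
undefined for untestable genomes, so those leaves are pruned from the tree
for fraction analyses; count traits use all genomes.

## Standardized multivariate regression

`fit_multivariate()` fits `Y = b0 + b1 X1 + b2 X2 + b3 X3 + e` by least
squares with an intercept on the raw per-genome variables — the contrast
analyses are origin-constrained, the regression deliberately is not; a
`regression_mode = "contrasts"` variant is available for sensitivity
checks. Standardization is full: `b_j = beta_j * sd(X_j) / sd(Y)` with the
sample (n−1) standard deviation, because only then are the `b`'s unit-free
and comparable across predictors. Exact rank deficiency is an error;
condition numbers above `1e8` produce a warning with variance-inflation
factors. `predictor_redundancy()` reports the plain Pearson correlation
between the global-regulator and NAP fractions, flagging `|r| > 0.7`: when
two predictors are that collinear their separate coefficients should not
be over-interpreted.

# The synthetic data model

`reduction_scenario()` fixes the study conditions; `simulate_scenario()`
generates every input the pipeline reads.

* **Phylogeny.** A Yule pure-birth tree (`simulate_tree()`, birth rate 1),
  ultrametric, 64 leaves by default.
* **Reference network.** Exact node and edge totals (60 TFs, 5 sigma
  factors, 400 target genes, 1000 interactions by default — roughly a 1:3
  scale-down of a real enterobacterial reference; the generator hits the
  full-scale 1784-node / 4058-interaction totals exactly when asked).
  Out-degrees are Zipf-like, the biggest regulons go to dual-typed TFs,
  and the top dual hubs carry the NAP flag, so type, globality and NAP
  function co-occur as they do in curated networks. Type proportions
  default to 0.35/0.37/0.25 activator/repressor/dual with 3% unclassified,
  mirroring the classified fraction of a curated TF set.
* **Gene loss.** Every gene is present at the root and is lost along a
  branch of length `t` with probability `1 - exp(-lambda * t * m)`,
  irreversibly (a ratchet: no regain). Hazards per unit branch length
  default to activator 0.8, repressor 0.5, dual 0.1, target genes 0.3,
  unclassified 0.5, sigma 0.05 — the hazard ordering *is* the ground truth
  the pipeline must recover; sigma factors are nearly immortal because
  housekeeping sigma survives even extreme reduction. The multiplier `m`
  is lineage-specific: its log evolves as Brownian motion along the tree
  (`rate_sd = 0.75` per square-root unit of branch length). This matters:
  on an ultrametric tree with homogeneous hazards every leaf has the same
  expected loss, so genome size and TF-type fractions would be
  uncorrelated across leaves and there would be no gradient to detect.
  Heritable intensity variation creates phylogenetically clustered,
  heavily reduced lineages — the endosymbiont-clade pattern — and `rate_sd`
  was chosen so simulated genome sizes span roughly the 30-fold range seen
  between free-living enterobacteria and the tiniest symbionts. With
  `rate_sd = 0` the model is homogeneous and per-type survival has the
  closed form `exp(-lambda * depth)`, which is how the generator is
  validated.
* **Genome size.** `size = intercept + 1000 bp x surviving genes +
  Normal(0, 10 kb)`, floored at 1 — about a kilobase per gene, at the
  generator's reduced gene-count scale. Leaves are binned into the four
  lifestyle categories (free-living, host-restricted, obligate, tiny) by
  descending quartile of surviving gene count; the labels exist for report
  parity and play no role in the statistics.
* **Hit tables.** Every present gene gets a reciprocal forward/reverse
  BLAST-tabular pair passing the thresholds (identity U(35,95), e-value
  10^-U(8,50), coverage > 0.7). A 10% decoy fraction adds hits that each
  fail exactly one acceptance predicate (identity, e-value, coverage) or
  reciprocity; decoys carry e-values worse than the genuine hit so they
  never displace a best hit, which is what makes "the map is unchanged by
  decoys" a well-defined invariant under the best-then-filter semantics.
  No sequences are simulated — hit tables are synthesized directly.

## What passing tests do and do not show

The generator produces exactly the effect structure the statistics are
built to detect: typed hazards, Brownian lineage intensity, clean
reciprocal hits. Real data add everything the generator omits — horizontal
transfer and gene gain, paralogy confusing best-hit orthology, annotation
errors in TF types, non-Brownian trait evolution, and reconstruction false
positives at larger distances. Recovery on synthetic data therefore
validates the machinery, not the biology: it shows the pipeline finds a
differential-conservation signal when one exists and stays quiet when the
hazards are equal, nothing more.

# Numerical conventions and problem sizes

* All randomness flows through explicit integer seeds; identical seeds
  give byte-identical outputs (scenario generation, polytomy resolution,
  reports).
* The hypergeometric tail is validated exhaustively against direct
  enumeration for all parameter sets with `N <= 12`; Fisher combination
  against the even-df chi-square closed form.
* Contrast calibration uses 20 replicate Brownian simulations on 64-leaf
  Yule trees; the end-to-end recovery check runs the default 64-genome
  scenario across 10 seeds. These sizes keep the default validation run in
  tens of seconds while leaving Monte-Carlo error well inside the asserted
  bounds.
* Regression coefficients are checked against an explicit
  normal-equations oracle at `1e-10`; predictors in the packaged example
  are kept at order-one scale (Mbp, fractions) so the oracle's cross
  product is well conditioned.

# Known limitations

* One-to-one orthology only: paralog families collapse to a single best
  pair, and lineage-specific duplications are invisible.
* The conservation test conditions on `n`; it measures composition among
  survivors, not absolute retention.
* Through-origin df (`contrasts - 1`) is a convention; with few genomes
  the t-approximation is rough.
* The globality decile cutoff is operational; rankings near the boundary
  should not be over-read.
* Fisher's method assumes independent tests; genomes sharing most of their
  history violate this, which is precisely why the contrast analyses, not
  the combined p-values, carry the correlational claims.
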