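# regulogr

Differential conservation of transcription-factor types in bacteria with
reduced genomes.

Endosymbiotic and obligately host-associated bacteria lose genes on their
way to tiny genomes, and regulatory genes go first. `regulogr` asks a
specific question about that process: as genomes shrink, are **activators**,
**repressors** and **dual regulators** lost at the same rate, or is one type
preferentially retained? The package implements the complete comparative
workflow needed to answer it, and a synthetic genome-reduction generator so
the whole analysis runs end to end from a seed, with no external data.

It is aimed at comparative genomicists and systems biologists studying
transcriptional regulatory network (TRN) evolution.

## The method

1. **Regulog reconstruction.** Orthologs between a reference proteome and
   each target genome are called by bidirectional best hits over BLAST
   tabular output, accepted when *e*-value < 1e-6, identity > 30% and
   alignment length > 60% of both proteins. A reference interaction
   TF → TG transfers to a genome when both endpoints have orthologs.
2. **Conservation tests.** For a reference coding *N* TFs with *K* of a
   focal type, a genome conserving *n* TFs of which *k* are of the type is
   tested one-sided (H0: f_i ≤ f_r vs H1: f_i > f_r, with f_i = k/n,
   f_r = K/N) by the hypergeometric upper tail P(X ≥ k). Per-genome
   p-values combine across genomes by Fisher's method,
   X = −2 Σ ln p ~ χ²(2m).
3. **Globality metric.** Each TF *x* gets

   G(x) = ¼ · ( TFR(x)/(N_TF+N_SF−1) + GR(x)/N_G + SF(x)/N_SF + CR(x)/(N_TF−1) )

   where TFR counts regulators regulated by *x*, GR its non-regulatory
   targets, SF the sigma factors and CR the other TFs sharing targets with
   *x*. G ∈ [0, 1]; the top decile are flagged global regulators.
4. **Phylogenetic correction.** Cross-genome correlations between genome
   size and each TF-type frequency/fraction are computed on Felsenstein's
   standardized independent contrasts, positivized, with correlation and
   regression through the origin (df = contrasts − 1).
5. **Standardized regression.** Each TF-type fraction is regressed on
   genome size, global-regulator fraction and NAP (nucleoid-associated
   protein) fraction; standardized partial coefficients
   b_j = β_j·sd(X_j)/sd(Y) compare predictor strength.

## Worked example

The default scenario simulates 64 genomes descending from a 60-TF reference
network, with per-type loss hazards activator 0.8 > repressor 0.5 > dual 0.1
(target genes 0.3) and lineage-heterogeneous loss intensity:

```r
library(regulogr)
study <- run_reduction_study(reduction_scenario(), seed = 1)
study
#> Genome-reduction conservation study
#>   64 genomes (0 untestable: no conserved TFs)
#>   Fisher-combined conservation p-values:
#>     activator  p = 1
#>     repressor  p = 1
#>     dual       p = 4.09e-135
#>   Through-origin contrast correlations with genome size:
#>     ...
#>     frac_activator  r = +0.446 (p = 0.000221)
#>     frac_repressor  r = +0.346 (p = 0.00505)
#>     frac_dual       r = -0.495 (p = 3.27e-05)
#>     ...
```

Reading: the activator and repressor fractions *fall* with genome size
(positive contrast correlation with size), the dual fraction *rises* as
genomes shrink (negative correlation), and only dual regulators are
preferentially conserved by the combined hypergeometric test — the
signature encoded in the generator's hazard ordering, recovered by the
pipeline.

The globality metric on its worked-example network:

```r
net <- example_global_regulator_network()   # 17 nodes, 26 interactions
globality_score(tf_regulatory_stats(net, "TF_G"), network_summary(net))
#> [1] 0.8272727
head(rank_global_regulators(net), 2)
#>   tf_id TFR GR SF CR         G rank is_global
#> 1  TF_G   2 10  2  3 0.8272727    1      TRUE
#> 2  TF_1   0  2  1  1 0.2537879    2     FALSE
```

File-based runs use `write_scenario()` + `run_full_analysis()`, or the
shell wrapper:

```sh
Rscript inst/scripts/regulogr.R simulate --leaves 16 --seed 7 --out scn
Rscript inst/scripts/regulogr.R config --init scn/config.txt --dir scn
Rscript inst/scripts/regulogr.R run-all --config scn/config.txt
```

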