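# urbanmeth

Differential DNA methylation analysis for urban-versus-forest habitat
comparisons from reduced representation bisulphite sequencing (RRBS),
with matched gene-expression modelling.

## The problem this package addresses

Comparative epigenomics studies of wild populations — for example, great
tits (*Parus major*) sampled from a city and a nearby forest — ask whether
habitat is associated with genome-wide changes in CpG methylation, whether
such changes concentrate in regulatory sequence, and whether they relate to
gene expression. The analysis chain behind those questions is long:
per-cytosine coverage files must be destranded and filtered, CpG islands
must be located from sequence alone, sites must be tested one by one with a
multiple-testing correction, nearby sites must be grouped into regions, and
every over-representation statement needs a carefully constructed
background. `urbanmeth` implements that chain end to end for a two-habitat,
two-group design, together with a synthetic-data generator that produces
data with known ground truth so every stage can be validated by parameter
recovery.

The package is aimed at analysts who have Bismark-style coverage files, a
genome FASTA, gene models, and (optionally) a gene-level expression count
table and GO annotation, and who want a tested, scriptable reimplementation
of this analysis at desk scale.

## The statistics at the core

* **Site testing.** For CpG unit *s* with methylated/total read counts
  (m<sub>ij</sub>, t<sub>ij</sub>) in sample *j* of group *i*, the habitat
  effect is tested by binomial logistic regression of per-read methylation
  state on habitat; with a single binary covariate the likelihood-ratio
  statistic has the closed form
  G = 2[ℓ(p̂ᵤ) + ℓ(p̂_f) − ℓ(p̂₀)] ~ χ²₁, where p̂ᵤ, p̂_f, p̂₀ are the
  pooled urban, forest and overall methylation proportions. The effect size
  is Δ = 100·(mean urban fraction − mean forest fraction). A DMS requires
  |Δ| > 25 (strict) and q < 0.01 (strict).
* **SLIM q-values.** q = π̂₀ · p<sup>BH</sup>, where π̂₀ is the slope of
  the most stable linear segment of the p-value empirical CDF over a
  sliding λ grid (bounded below by the right-tail estimate
  (1 − F(λ_max))/(1 − λ_max) and capped at 1).
* **Permutation null.** The full calling procedure (tests, q-values, both
  thresholds) is rerun under balanced random relabelings of the twelve
  individuals; p = (1 + #{null ≥ observed}) / (n_iter + 1) with the DMS
  count as statistic.
* **CpG islands.** Non-overlapping 100 bp windows; a window qualifies when
  the trailing average over up to 10 windows has GC ≥ 50% and CpG
  observed/expected = (N<sub>CG</sub>·L)/(N<sub>C</sub>·N<sub>G</sub>)
  ≥ 0.6; qualifying spans are merged and regions ≥ 200 bp reported. Shores
  are the flanking 2 kb, excluding island bases.
* **DMRs.** Greedy left-to-right chaining of DMSs: a region requires ≥ 3
  sites spanning ≤ 2 kb; direction class is constitutive
  (all hyper / all hypo) or mixed.
* **Over-representation.** 2×2 tables of focal vs background site sets with
  the cross-product odds ratio (a/b)/(c/d) and two-sided Fisher exact p;
  backgrounds are the relaxed-coverage site set (≥ 3 reads in ≥ 1 sample)
  or, for DMR-restricted tests, sites within 2 kb of ≥ 2 other sites. GO
  over-representation uses one-sided hypergeometric tests after true-path
  propagation, with Benjamini-Hochberg FDR.
* **Methylation-expression model.** expression ~ methylation × feature
  (gene body / promoter / TSS) with a random intercept per individual,
  refit as a fixed-effects model when the random-effect variance estimate
  is zero; per-feature slopes with 95% CIs and Tukey-adjusted pairwise
  slope differences (studentized range over three groups).

## Worked example

Simulate a study at the default conditions (6 + 6 samples, ~4,000 assayed
CpG units with median methylation near 10%, 30 planted differential sites
with shifts > 25 percentage points, planted CpG islands, and expression
negatively coupled to TSS methylation), then run the full pipeline:

```r
library(urbanmeth)

study  <- simulate_study(sim_config(rng_seed = 7L))
result <- run_pipeline(run_config(seed = 7L), study = study)
print(result)
#> pipeline_result
#>   3907 united CpG units (background 4000), 12 samples
#>   30 DMSs (pi0 = 1.000), 5 DMRs, 8 CpG islands
#>   TSS methylation-expression slope -0.02361

result$feature_enrichment$cgi_shore
#> enrichment_result [cgi_shore]
#>   focal 4/30 vs background 197/4000
#>   odds ratio = 2.97 (over), p = 0.0596

summary(result$expression_fit)
#> meth_expr_fit: 360 observations, fixed-effects fit (random-intercept variance 0)
#>   interaction: F(2, 354) = 11.3, p = 1.77e-05
#>   gene_body  slope -0.02542  [-0.03494, -0.01589]
#>   promoter   slope +0.0002199  [-0.006552, 0.006992]
#>   tss        slope -0.02361  [-0.03763, -0.0096]
#>   pairwise slope differences (Tukey-adjusted):
#>     gene_body - promoter   -0.02564  p = 6.15e-05
#>     gene_body - tss        -0.001805  p = 0.976
#>     promoter - tss         +0.02383  p = 0.00782
```

Reading the output: of 3,907 CpG units covered at ≥ 10× in all twelve
samples, 30 passed both DMS thresholds, and five clusters of three or more
DMSs within 2 kb were reported as DMRs; all eight planted CpG islands were
detected. The expression model recovers the planted negative TSS coupling
(slope ≈ −0.024 log2 units per methylation percentage point, CI excluding
zero) and a flat promoter slope; the gene-body slope is also negative here
because habitat shifts both body methylation and expression of coupled
genes — a group-level confounding that real two-habitat designs share.

The same pipeline runs from files (Bismark coverage, FASTA, BED6 gene
models, count TSV) via the `coverage_files=` / `genome_fasta=` /
`genes_bed=` / `expression_tsv=` arguments of `run_pipeline()`, and each
stage is exported on its own (`read_coverage()`, `merge_strands()`,
`unite()`, `detect_cgi()`, `call_dms()`, `call_dmrs()`,
`feature_enrichment()`, `go_enrichment()`, `fit_meth_expr()`, ...).

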