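---
title: "Methods and design notes for urbanmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for urbanmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`urbanmeth` reimplements, as one tested pipeline, the post-alignment
analysis of a two-habitat RRBS comparison: site-level differential
methylation with a permutation null, sequence-based CpG-island detection
and genomic-feature annotation, region calling, over-representation
testing against purpose-built backgrounds, and a methylation-by-feature
model of gene expression. This vignette records the statistical model of
each stage, the package's default parameters and why they hold their
values, what the synthetic-data generator does and does not emulate, and
the design decisions taken where more than one reasonable reading existed.

## 1. From coverage files to a methylation matrix

Bismark-style coverage files report each cytosine separately per strand.
The two cytosines of one CpG dinucleotide measure the same methylation
unit, so `merge_strands()` locates CpG dinucleotides in the genome and sums
the read counts of the + strand C at position *p* and the − strand C at
*p* + 1 into a single unit anchored at *p*. The merged methylation level is
the pooled fraction (m₁+m₂)/(t₁+t₂), not the mean of the per-strand
fractions; records outside CpG context pass through unmerged with a
counter, since isolated non-CpG rows usually indicate an annotation or
genome-version mismatch worth surfacing rather than silently dropping.

Coverage filtering retains units with **≥ 10** total reads (inclusive) and
at most the per-sample **99.9th percentile** of coverage. The percentile is
computed with R's default linear-interpolation quantile; sites exactly at
the cap are retained and only strictly greater values removed, which is
the direct reading of a "more than the 99.9th percentile" rule. Filtering
is applied after strand merging, per sample, before intersection; a
`filter_before_merge`-style order can be had by calling the exported
stages in the other order, but merged-then-filtered is the default because
the coverage thresholds refer to the biological unit, not the strand read.
`unite()` then intersects the per-sample site sets — only units covered in
every sample are analysed — and orders sites by (chromosome, position) so
all downstream results are deterministic.

Two site universes coexist deliberately. The **analysis set** (10× in all
samples) feeds the site tests. The **relaxed background** (≥ 3 reads in
≥ 1 sample) approximates "everything the assay saw" and serves as the
reference set for over-representation tests; it is a superset of the
analysis set by construction, and the analysis sites are *not* removed
from it — enrichment is assessed relative to all sequenced sites, not to
the complement of the focal set.

Internally all coordinates are 0-based half-open; the Bismark dialect
(1-based inclusive) is translated only at the file boundary. This keeps
interval arithmetic (shores, promoters, clipping) free of off-by-one
ambiguity.

## 2. Site tests, SLIM q-values, permutation null

With aggregated counts per sample and a single binary covariate, the
binomial-logistic MLE pools counts within each group, so the
likelihood-ratio statistic reduces to the closed form

G = 2[ℓ(p̂ᵤ) + ℓ(p̂_f) − ℓ(p̂₀)],

evaluated on the pooled urban, forest and combined proportions, with
p-values from χ²₁. The closed form is verified against `glm()` in the test
suite and is what makes whole-matrix permutation affordable (one
permutation of a 4,000-site matrix costs milliseconds rather than 4,000
`glm` fits). No overdispersion correction is applied: samples within a
habitat share one proportion per site in the model, a known limitation
shared with the default behaviour of the standard RRBS toolchain. The
effect size reported alongside is the difference of group means of
per-sample methylation fractions, in percentage points — not the pooled
difference — because a per-sample mean is robust to one deeply sequenced
individual dominating the pooled counts.

A site is a **DMS** when |Δ| > 25 percentage points and q < 0.01, both
strict inequalities; a site at exactly 25.0 is not called.

**SLIM q-values.** The null proportion π₀ is estimated from the empirical
CDF of the p-values on the grid λ = 0.05, 0.10, …, 0.95: within each
sliding window of five grid points, the local point-to-point slopes are
computed, the window with the smallest slope variance (the most linear,
i.e. most signal-free stretch of the CDF) is selected, and its
least-squares slope is taken as π₀. Two guards apply: π₀ is bounded below
by the right-tail estimate (1 − F(λ_max))/(1 − λ_max), which handles
degenerate inputs such as a point mass of p-values at 1 (where every CDF
slope on the grid is zero yet π₀ is plainly 1), and bounded above by 1.
Then q = π₀ · p^BH, capped at 1 and made monotone in p. With fewer than
100 p-values the CDF is too coarse for segment fitting and the estimator
falls back to π₀ = 1 (plain Benjamini–Hochberg) with a warning.

**Permutation test.** The statistic is the number of called DMSs — the
full calling procedure, including re-estimation of π₀ and q-values, is
rerun in every iteration, so the null distribution reflects the whole
pipeline and not just the site test. Labels are permuted uniformly among
*balanced* reassignments (6 vs 6), sampled with replacement; only 924
distinct balanced splits exist, so occasionally a permutation reproduces
the observed labelling (or its mirror), which is why the minimum
attainable p is 1/(n_iter + 1) under the add-one estimator
p = (1 + #{null ≥ observed})/(n_iter + 1) and why, with strong signal, the
realized p is sometimes 2/(n_iter + 1) or 3/(n_iter + 1) rather than the
floor. An alternative statistic (mean |Δ| of called sites) is available
behind an argument.

## 3. CpG islands, shores, gene features

The island rule is a windowed composition test: GC content ≥ 50% and CpG
observed/expected ≥ 0.6 over an average of 10 windows of 100 bp, minimum
length 200 bp. Several published variants fit that description; the
package fixes the following reading. The chromosome is cut into
consecutive non-overlapping 100 bp windows. Per window, GC = (N_C+N_G)/L
and obs/exp = (N_CG · L)/(N_C · N_G), with L the window length (ambiguous
bases count toward L but not toward any base tally, so N-rich windows are
penalized rather than inflated), obs/exp defined as 0 when a window has no
C or no G, and a CG dinucleotide credited to the window containing both of
its bases. A window *qualifies* when the trailing mean over up to 10
windows (itself plus up to nine predecessors) passes both thresholds. The
reported island is the union of the *spans those qualifying averages were
computed over*, merged, with regions shorter than 200 bp discarded.
Reporting the averaged span, rather than the qualifying windows alone, is
what makes the detector's localization usable: a trailing average lags the
composition change by construction, so the qualifying windows sit at the
right edge of the true island, while the averaged span covers it. The cost
is a modest overhang into the flanks (about 1–2% of background bases on
simulated genomes, measured in the test suite); the benefit is ≥ 95%
base-level recovery of planted islands. A `per_window = TRUE` switch
qualifies each window on its own composition for sensitivity analysis.

Shores are the 2 kb flanks on each side of every island, clipped to the
chromosome, with bases inside any island excluded and overlapping shores
merged — the gap between two islands 1 kb apart is one shore, counted
once. Gene features are strand-aware around the 5′ start *g*: TSS region
[g−300, g+50), promoter [g−3000, g−300) (upstream of the TSS region,
excluding it), gene body the full annotated span, mirrored on the − strand
and clipped to chromosome bounds; overlapping same-class intervals of one
gene are merged before any counting. A site may carry several feature
flags at once (a first-exon site is both TSS and gene body);
"nonregulatory" is defined as carrying none, and the complement identity
is asserted in the tests. Whether a gene body should exclude its TSS
overlap is not decided by the definitions above; the package keeps the
full span, consistent with multi-membership counting.

## 4. DMRs

A DMR is ≥ 3 DMSs within a 2 kb window. "Within a window" is implemented
as greedy left-to-right chaining: starting at the leftmost unassigned DMS,
the chain absorbs following DMSs while the span from first to last member
(inclusive) stays ≤ 2,000 bp; maximal chains with ≥ 3 members are
reported, and every DMS belongs to at most one DMR. This produces the
countable, non-overlapping regions that summary statements ("19 DMRs
involving 102 DMSs") require, whereas a literal sliding window yields
overlapping windows that cannot be counted without a deduplication rule —
the greedy chaining *is* that rule, and the test suite proves it equal to
an exhaustive enumeration of all 2 kb windows followed by leftmost-first
deduplication on every random instance up to 50 sites. Direction classes:
`constitutive_hyper` / `constitutive_hypo` when all members agree, else
`mixed`. A dense cluster (e.g. dozens of sites within 300 bp) is a single
DMR under this rule, as it should be.

## 5. Over-representation

All 2×2 tests report the sample cross-product odds ratio (a/b)/(c/d) — the
estimator that reproduces the published table-derived values — alongside
the two-sided Fisher exact p-value; the conditional-MLE estimate that
`fisher.test()` would report differs slightly in finite samples and is not
used. Degenerate tables (a zero margin) yield an odds ratio of 0 or
infinity with an explicit flag rather than a continuity correction,
matching how an all-focal-sites-in-class result should be reported.

A gene is **expressed** when its raw count is ≥ 10 in at least
⌈0.25 · n⌉ samples (3 of 12). The expressed-gene site property is "linked
via promoter, TSS or gene body to ≥ 1 expressed gene". For the
DMR-restricted variant the focal set is DMSs inside DMRs, and the
background is thinned to sites with ≥ 2 other sites within a 2 kb span
(the same span convention as the DMR rule), so that the background carries
the same clustering opportunity as the focal set.

GO over-representation propagates annotations along `is_a` and `part_of`
edges (true-path rule; evidence codes are not filtered), then applies
one-sided hypergeometric upper-tail tests to every term with at least one
focal gene, with Benjamini–Hochberg FDR across tested terms. The universe
defaults to genes with ≥ 1 propagated annotation; genes without ontology
information are reported as excluded rather than silently counted, and a
`background = "all"` option keeps them in the universe for sensitivity
analysis. Semantic-similarity reduction of the resulting term list is out
of scope; full term tables are returned.

## 6. The methylation-expression model

Observations are one row per (DMS, gene, feature, sample): a DMS inside
two features of one gene contributes a row per feature, and methylation is
the sample's observed percentage at that site. Expression is
`log2(count/sf + 1)` after median-of-ratios size factors — a deliberate,
documented approximation to the regularized-log transform: it removes
library-size differences and stabilizes the scale without the shrinkage
component, and the model's structure (slopes by feature and their
interaction), not the transform's shrinkage detail, is what the stage
exists to test. Only genes passing the expressed-gene rule enter the
observation table; genes below it have counts too sparse for a meaningful
log-scale response and would contribute pure-noise rows.

The model is `expression ~ methylation * feature` with a random intercept
per individual. When the REML variance estimate of that intercept is below
1e-8 — the expected outcome once size factors have absorbed
individual-level depth differences — the model is refit by ordinary least
squares and all reported quantities come from that fit. Per-feature
marginal slopes and their 95% t-intervals come from contrast vectors on
the coefficient covariance; pairwise slope differences are adjusted by the
studentized range over three groups (`ptukey` with the residual df), and
the implementation is checked against `emmeans::emtrends()` in the test
suite. Observation rows from one gene share a baseline and are treated as
exchangeable given the individual intercept; this pseudo-replication is
knowingly ignored, matching the degrees of freedom such models report in
practice, and is the main caveat on the reported intervals.

## 7. What the generator emulates, and what it does not

`sim_config()` defaults are the study conditions all tests run under:

| parameter | default | rationale |
|---|---|---|
| samples | 6 urban + 6 forest | the two-habitat design size |
| genome | 1 chromosome, 500 kb | desk-scale; names `chr1…chrN` |
| baseline methylation | Beta(0.35, 1.31) | median 0.10, SD 0.25: a right-skewed, hypomethylated majority |
| coverage | NB(mean 25, size 60) per unit | the 10–35× working range; size 60 keeps nearly all sites above the 10× filter in all 12 samples, so ground truth stays observable |
| assayed units | 4,000 sampled CG dinucleotides | RRBS covers a subsample of genomic CpGs |
| planted DMSs | 30; effect +/−0.40 | comfortably above the 25-point calling floor |
| clustering | 60% of non-TSS planted sites in trios ≤ 2 kb | gives the DMR caller true regions |
| genes | 100, 1.5–3.5 kb, both strands | enough genes that coupled genes stay a small fraction (composition bias in size factors stays negligible) |
| non-expressed fraction | 0.25 | exercises the expressed-gene rule |
| TSS slope | −0.03 log2 per methylation % | the planted coupling the model must recover |
| islands | 8 per genome, 800–1,200 bp, GC ≈ 68%, obs/exp ≈ 1 | realistic island composition that clears the detector thresholds with margin under 10-window averaging |

Background sequence is drawn i.i.d. at A/C/G/T = 0.3/0.2/0.2/0.3 and 78%
of CG-completing Gs are rewritten, giving GC ≈ 37–40% and CpG obs/exp
≈ 0.26 — vertebrate-like CpG depletion. Methylation shifts are additive on
the proportion scale with clipping to [0.01, 0.99]; a clipped site is
recorded as a true DMS only if its realized shift still exceeds 25 points,
so hypomethylation planted on an already-low baseline is honestly dropped
from the truth set. Coverage is drawn per strand (size/2, mean/2 per
strand, so the merged unit is exactly NB(mean, size)), and the writer
emits genuine two-rows-per-unit Bismark dialect, exercising the strand
merger.

Three generator choices exist purely to keep planted parameters
identifiable and are worth knowing when interpreting recovery tests:
TSS-coupled sites are singletons, one per gene (a gene's expression
responds to a single planted TSS site; clusters and singletons avoid TSS
regions), because a gene responding to the mean of several sites makes
every per-site regression attenuated by construction; coupled genes stay
expressed and their baselines are drawn from a narrow band in the
upper-middle of the expression range, so the gene-blind pooled model is
not dominated by between-gene baseline spread and counts stay off the
floor where `log2(x + 1)` flattens; and expression responds to the
*realized* (observed) methylation of the coupled site, so recovery tests
measure the model, not an attenuation from simulated measurement error.
Even so, the pipeline's fitted TSS slope runs ~5–10% shallow of the
planted −0.03 on average — residual curvature of the approximate
transform plus mild size-factor composition bias — which is representative
of what the approximation costs on real data.

Not emulated: positional autocorrelation of coverage, bisulphite
conversion error, SNPs destroying CpG sites, read-level artefacts,
non-CpG methylation, and any alignment-stage effect. Passing recovery
tests therefore validates the statistics given faithful counts, not
robustness to upstream artefacts.

## 8. Numerical conventions and degenerate inputs

* 0·log(0) terms in the binomial log-likelihood are defined as 0; the LR
  statistic is floored at 0 before the χ² tail.
* All-zero or all-full sites give G = 0, p = 1, Δ as computed.
* Quantile caps use `type = 7` quantiles; boundary values are retained.
* `enrichment_test` validates non-negative integer counts and refuses a
  table that is empty on both rows.
* `transform_counts` refuses an all-zero sample (undefined size factor).
* OBO parsing keeps only `[Term]` stanzas, drops `is_obsolete` terms, and
  follows `is_a` and `relationship: part_of` edges.
* Ties in DMR chaining cannot arise: sites are totally ordered by
  (chromosome, position) and chains are maximal by construction.
* Every randomized stage takes an explicit seed (`sim_config(rng_seed=)`,
  `permutation_test(seed=)`, `run_config(seed=)`); with fixed seeds all
  outputs, including written files, are byte-identical across runs.

## 9. Test-suite problem sizes

The suite validates each stage at sizes chosen for tight feedback loops:
a 200 kb / 1,500-unit study for the shared fixture, the full 500 kb /
4,000-unit defaults for end-to-end parameter recovery, 5,000 sites for
null-uniformity checks, 10,000 p-values for π₀ calibration, 100
permutation iterations for null behaviour (the full 1,000 iterations are
used by the acceptance script's single run), 20 replicates for
CI-coverage and null-interaction rates, and exhaustive oracles at n ≤ 50
(DMR windows) and N ≤ 12 (hypergeometric enumeration). These are the
package's own desk-scale choices and are asserted in
`tests/testthat/test-acceptance.R`.

## 10. Known limitations

* No overdispersion / beta-binomial layer in the site test; biological
  replicate variability beyond binomial sampling inflates significance on
  real data.
* The rlog approximation is not the shrinkage transform; low-count genes
  are noisier than under the genuine regularized log.
* Gene-level correlation among observation rows is ignored (Section 6),
  so expression-model intervals are approximate.
* The CGI detector reports averaged spans (Section 3) and so slightly
  overhangs true island boundaries.
* Single-chromosome defaults mean positional effects spanning chromosomes
  are untested; multi-chromosome configs are supported but slower.
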