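---
title: "Methods and design of the methage differential-methylome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the methage differential-methylome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methage)
```

## The analysis problem

`methage` implements a complete two-group differential DNA-methylation
analysis for bisulfite-sequencing count data, of the kind used to compare
sperm or preimplantation-embryo methylomes between advanced-paternal-age
(APA, ≥ 50 years) donors and young controls (≤ 35 years). The input is a
set of per-sample coverage tables (one row per CpG: methylated and
unmethylated read counts); the outputs are per-CpG test results,
directional differentially methylated regions (DMRs), genomic-context
annotation, enrichment statistics, chromosomal localization profiles, and
clustering/regression summaries.

Because raw human sperm and embryo sequencing data are access-controlled,
the package ships a synthetic-data generator with known spiked truth, and
every downstream stage is validated against it.

## Models and procedures

### Per-CpG testing

Methylation at a CpG is the fraction of reads reporting a cytosine
(unconverted) over all reads covering the site, times 100. Sites are
retained only when **every** sample in both groups has at least
`min_coverage` reads (default 5; this is the strictest reading of a
minimum read-count filter, and it keeps the per-sample percentage defined
everywhere). At 5 reads the assay's theoretical resolution — the smallest
nonzero representable methylation step — is 100/5 = 20%.

Two test designs are provided, matching the two study arms such data come
from:

* **t-test design** (replicated samples, e.g. sperm): each sample
  contributes one percentage per site; groups are compared with a
  two-sided unpaired t-test. The package defaults to the Welch
  (unequal-variance) form because group sizes of six give no protection
  against heteroscedasticity; the pooled-variance Student form is
  available via `var_equal = TRUE`. Sites where both groups are constant
  get p = 1 when the means agree and p = 0 when they differ.
* **Fisher design** (single-embryo samples): counts are pooled within
  each group into one 2×2 table (group × methylation state) per site and
  tested with the two-sided Fisher exact test (minimum-likelihood rule).
  Group means and the effect size Δ (APA − young, in percentage points)
  are still computed from per-sample percentages so both designs report
  comparable effects.

A calibration caveat worth stating explicitly: pooling counts across
individuals treats reads, not donors, as the sampling unit. Under
inter-individual overdispersion the pooled Fisher design is therefore
intrinsically anti-conservative at the single-CpG level (we observe
roughly 15% of null sites at p ≤ .05 under the default beta-binomial
noise, against ~4% for the t-test design, and ~4% for Fisher when the
noise is purely binomial). This is a property of the design, not of the
implementation; the windowed DMR rule below is the false-positive control
for both designs.

### DMR calling

The caller implements a windowed, direction-aware rule:

1. keep significant sites (p ≤ α, default .05, with Δ ≠ 0);
2. per chromosome, partition them into clusters by cutting wherever the
   gap to the previous significant site exceeds `lambda_bp` (default
   1000 bp);
3. within a cluster, for each direction independently, the significant
   sites of that sign form a DMR when there are at least `min_cpgs` of
   them (default 3; array mode uses 2) and the absolute mean of their
   deltas is at least `min_mean_abs_delta` (default 10 percentage
   points).

A cluster can emit at most one hypermethylated and one hypomethylated
DMR; this deliberately permits loci carrying both directions. The DMR
span is the half-open interval from its first to one past its last member
CpG, so three adjacent CpGs can legitimately produce a span of just a few
bp. The mean delta is taken over the DMR's own-direction significant
members by default; `mean_over = "all"` averages every tested CpG in the
span instead (both conventions appear in the literature, and the choice
is reported in the output). A kernel scaling constant (`kernel_C = 75`)
is carried in the configuration for provenance with kernel-based callers
but plays no role in the windowed rule: the membership filters, not a
smoothing kernel, define the regions here. The caller is verified against
an independent brute-force implementation (full pairwise adjacency +
graph components) on hundreds of random inputs.

### Annotation

CpG-island context uses the conventional ring definitions: shores are the
2 kb flanks of (merged) islands, shelves the next 2 kb beyond the shores,
everything else open sea; the three rings are disjoint by construction
and a DMR's context is the highest-precedence context (island > shore >
shelf) of any member CpG. Gene association is by overlap with the gene
body or the strand-aware promoter window `[tss − 2000, tss + 500)`
(mirrored on the minus strand); a DMR overlapping several genes counts
for all of them. Cytobands must cover every chromosome carrying DMRs;
nucleosome-retention colocalization is reported both as bp overlap per
DMR and through gene-list enrichment.

### Enrichment statistics

Every enrichment in the package reduces to a 2×2 table: Fisher exact
p-value, sample cross-product odds ratio, and a Woolf log-OR 95%
confidence interval, with the Haldane–Anscombe +0.5 correction applied to
all four cells when any cell is zero (for the OR and CI only, never the
p-value). Benjamini–Hochberg adjustment is applied within each analysis
family (across cytobands, across disease lists), never pooled across
families. The gene universe defaults to all symbols in the supplied gene
models; a `covered` option restricts it to genes containing at least one
tested CpG — the choice materially changes odds ratios, so it is explicit
in the interface and recorded in the manifest.

### Localization by kernel density

Gene start sites per chromosome are smoothed with an exact Gaussian
kernel density evaluated on a uniform grid (default 512 points), with
bandwidth 0.2 × Silverman's rule-of-thumb value — the standard "adjust"
semantics of R's `density()`. The estimate is computed as a literal sum
of Gaussians rather than via FFT binning so that it is exactly
reproducible and testable against a first-principles oracle. 95%
confidence bands come from a seeded nonparametric bootstrap (resample
sites with replacement, re-derive the bandwidth, recompute; 10,000
resamples by default, fewer in tests). A cytoband is flagged as divergent
when the DMR-gene band and the all-gene band are disjoint over at least
half of the grid points inside it. This flagging rule is an explicit
design choice: published figures of this kind highlight bands without
stating a criterion, so the package uses a conservative, configurable one
and reports it.

### Downstream analyses

Member CpGs of all DMRs are z-scored per site (positive = hypermethylated
relative to the site mean) and samples are clustered on correlation
distance (1 − Pearson by default; the package treats "rank correlation
with Pearson" phrasing found in methods sections as Pearson-on-values,
with a Spearman option) with average linkage; the two-group cut is
scored against the known labels by adjusted Rand index. Age association
is simple OLS of methylation on age with the two-sided slope p-value;
group comparisons report both t-test and Mann–Whitney U p-values
(exact for group sizes ≤ 12 without ties). The 450K-style adapter runs a
per-probe Welch t-test on β-values, converts deltas to the percent scale,
and feeds the same DMR caller in array mode (`min_cpgs = 2`); the
10-point mean-difference filter is retained for β data by default
(|Δβ| ≥ 0.10), configurable.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions every recovery figure in this package refers to:

* two groups of six samples; ages uniform on [25, 35] (young) and
  [50, 64] (APA);
* two 1 Mb chromosomes, 20 CpG islands of 1 kb per chromosome with 15
  CpGs each, background CpGs at 5 × 10⁻⁴ per bp;
* sperm-like baselines: islands ~10% methylated, background ~80%;
* beta-binomial inter-individual noise with overdispersion ρ = 0.05
  (binomial sampling alone would make the t-test unrealistically
  powerful), read depth Poisson with mean 20;
* 8 hypermethylated and 8 hypomethylated spiked regions of effect 30
  percentage points, each a CpG island (≥ 3 CpGs, in practice 15).
  Islands chosen for hypomethylation start from the methylated
  background baseline — methylation must exist before it can be lost —
  while hyper-spiked islands rise from the island baseline;
* genes tiled evenly with alternating strands, cytobands exactly
  partitioning each chromosome, nucleosome regions over 20% of
  promoters, and planted gene lists whose overlap fraction with the
  spiked-DMR-associated genes is configurable (0.5 for the planted list,
  proportional for the null list).

All generation is a pure function of the configuration, including its
seed. What the generator does **not** emulate: read-level artifacts
(bisulfite conversion error, mapping bias), strand asymmetry,
linkage-disequilibrium-like correlation between nearby CpGs beyond the
shared regional mean, SNP-overlapping CpGs, and realistic chromosome-
scale gene-density gradients. Passing recovery tests on this generator
therefore demonstrates the correctness of the statistical machinery under
a realistic noise model, not performance on any particular real cohort.

## Numerical and degenerate-input choices

* Zero-coverage rows are retained at read time but flagged, and excluded
  by the merge filter; methylation percentage is an error, not NaN, at
  zero reads.
* Zero-variance sites: p = 1 when groups agree (no signal), p = 0 when
  they are constant but different (perfect separation).
* Fully tied group comparisons return p = 1 for both tests.
* All-zero 2×2 tables are an error; single-zero cells trigger the
  Haldane–Anscombe correction for the OR/CI only.
* Degenerate bootstrap resamples that collapse onto one position fall
  back to a minimal positive bandwidth.
* Coordinates are 0-based half-open everywhere internally; 1-based
  inclusive inputs (Bismark coverage dialect) are converted at read time
  and never downstream.
* Every stochastic stage (simulation, bootstrap) takes an explicit seed
  and restores the caller's RNG state.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run at deliberately modest
scales chosen to exercise every code path with tight Monte-Carlo error:
recovery studies use the default two-chromosome genome (~1,600 CpGs × 12
samples) over 10–50 seeds; null calibration uses a ~10,000-CpG no-effect
genome; the gene-set and cytoband detection rates use constructed
universes of 5,000 and 1,000 genes over 50–100 replicates; bootstrap
bands in tests use 150–200 resamples (the analysis default remains
10,000). These sizes are the package's own verification design.

## Known limitations

* The pooled Fisher design's single-CpG anti-conservatism under
  overdispersion, discussed above.
* The windowed caller has no region-level p-value or FDR; the window
  rule plus the mean-delta filter are the only false-positive controls,
  as in the analysis style it reproduces.
* Printed odds ratios from studies of this design depend on an
  unstated gene universe and are therefore not directly reproducible;
  the package makes the universe explicit instead.
* The band-flagging criterion is a package convention; other reasonable
  criteria (e.g. pointwise tests with multiplicity control) would flag
  slightly different band sets.

## A worked example

```{r example, eval = FALSE}
library(methage)

study <- run_simulation_study(sim_config(seed = 11))
study$report
#>   seed n_sites n_spiked n_dmrs sensitivity fdp ari
#> 1   11    1532       16     16           1   0   1
```

Sixteen spiked regions, sixteen called DMRs, every spiked region
recovered with the right direction, no false regions, and the two-branch
clustering cut reproduces the group labels exactly.
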