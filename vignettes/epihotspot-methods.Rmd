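---
title: "Methods: differential methylation, DMR classification and epimutation hotspots"
author: "epihotspot developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation, DMR classification and epimutation hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`epihotspot` implements a regional differential-DNA-methylation analysis for
small, family-structured patient/control cohorts profiled by reduced
representation bisulfite sequencing (RRBS). The data unit is a CpG site with
methylated and unmethylated read counts per sample; the scientific unit is a
differentially methylated region (DMR) tile, classified as *shared* across
families or *family-specific*, and then interrogated against chromatin
annotations, expression changes, and lamina-associated-domain (LAD)
reorganization.

The pipeline has three differential runs per cell type: all samples pooled,
family A only, and family C only. Running within families normalizes
family-private methylation background; the pooled run recovers effects shared
across families.

### Per-CpG test

For each united CpG position the package compares patient and control
methylated/unmethylated counts with a binomial likelihood-ratio test:
groupwise MLE rates $\hat p_g = \sum m_i / \sum t_i$ versus a pooled rate,
$\Lambda = 2(\ell_1 - \ell_0) \sim \chi^2_1$. This is exactly the deviance
test of the logistic regression `cbind(meth, unmeth) ~ group` (the
replicate-aware default of methylKit-style tools); the test suite asserts
equality with `glm()` to 1e-10. For 1-vs-1 designs a Fisher exact test on
pooled counts is available (`test = "fisher"`).

Multiple testing uses Benjamini–Hochberg across all tested positions. The
upstream tooling this emulates ships SLIM q-values; BH was chosen because it
is standard, monotone and exactly reproducible, and the choice is recorded in
the DMCpG output metadata. A differentially methylated CpG (DMCpG) must
satisfy both $q \le 0.01$ and an absolute mean-percent difference
$|\Delta| \ge 30$ points, where $\Delta$ = mean of patient per-sample percent
methylation minus the control mean (positive = patient hypermethylated).

### DMR tiles

DMCpGs within 500 bp of a neighbor merge into one tile (single linkage);
tiles with members of opposite sign are *ambiguous* and removed (the count is
reported); tiles below 100 bp are extended symmetrically to exactly 100 bp.
Three details are deterministic choices the method description leaves open:

* extension grows both sides by `ceiling(deficit/2)` and trims one bp from
  the right when parity overshoots; at coordinate 0 the remainder is pushed
  right;
* ambiguity is evaluated *before* extension, so extension can never
  resurrect a removed region;
* a tile over member positions $p_1..p_k$ spans $[p_1-1, p_k)$ in 0-based
  half-open coordinates before extension.

### Shared / family-specific classification

A tile (from any of the three runs) is *eligible* only if its span contains
at least one united CpG position in both family matrices. "Found in" a run
means $\ge$ 1 bp overlap with any tile of that run (`min_overlap_bp` is
configurable; 1 bp is the weakest consistent reading of "found in"). A tile
found in exactly one family run is family-specific (with or without the
pooled run); found in both family runs, or only in the pooled run, it is
shared.

Cross-cell-type persistence assigns each region a (fibroblast state, iPSC
state) pair over {hyper, hypo, none}, eight classes excluding (none, none);
when a region overlaps multiple tiles of one cell type, the largest overlap
wins (ties: leftmost).

## Interval engine

All genomic arithmetic runs on a native engine with BEDTools semantics:
`intersect` (a-pieces truncated to the overlap, plus the distinct-a count),
`subtract`, `closest` (gap in bp, 0 when overlapping or bookended, ties to
the smaller start, unreachable chromosomes reported as NA), and gap-merge.
Coordinates are 0-based half-open everywhere internally; 1-based CpG
positions convert at the I/O boundary. Property tests check the engine
against brute-force all-pairs and per-base-mask oracles, base-count
conservation of subtract+intersect, and merge idempotency.

`lad_redistribute` defines Gain of LAD = subtract(disease, control), Loss =
subtract(control, disease), Maintenance = intersect. Inputs are unioned
(overlapping/bookended intervals merged) first so that
|GoL| + |MoL| = |disease LADs| holds exactly even for self-overlapping input
BEDs. The cross-cell-type filter keeps GoL intervals with *no* fibroblast-LAD
overlap and LoL/MoL intervals *with* one.

## Enrichment statistics

Odds ratios use the 2x2 table a/b/c/d where a = focal CpGs in the context,
b = focal CpGs outside, and c/d count the background *minus* the focal set
(the complement reading of the formula's wording); significance is two-sided
Fisher's exact, one-tailed only in the inter-cell-type binned proximity test.
log10 OR is reported; zero margins are flagged rather than corrected.
TSS-distance enrichment bins signed distances to the *nearest* TSS (per-gene
counting with multiplicity would double-count background CpGs in the 2x2
table); a CpG exactly at a TSS is downstream, bin [0, 1) kb. Gene association
uses the basal-plus-extension rule: basal domain 5 kb upstream / 1 kb
downstream of the TSS, extended to the nearest neighboring basal domain or
1 Mb; tiles associate to every gene whose regulatory domain they touch.

Promoters are the 2 kb upstream of the TSS treated as a 0-based boundary
(a + strand TSS at 10,000 has promoter [8000, 10000); minus strand mirrored).
Feature assignment is mutually exclusive with precedence
promoter > exon > intron > intergenic, matching the way RRBS feature
fractions are conventionally reported as a partition.

## Expression and proximity integration

Direction concordance pairs every (tile, associated DEG) and summarizes the
signed plane by the quadrant count ratio
QCR = (n_I + n_III - n_II - n_IV) / N. Points on an axis (zero methylation
difference or zero fold change) are excluded from the counts *and* from N:
the formula defines only four quadrants, and exclusion is the conservative
reading. DEG tables are filtered by FDR <= 0.05 (fibroblast source) or
p <= 0.05 (cardiac source) before intersection into "conserved DEGs"; the
2 Mb LAD-distance odds ratio uses all other genes of the supplied model as
background (configurable), with gene position = full gene body and distance 0
on overlap.

### Hotspot proximity test

The observed statistic is each query CpG's distance to the nearest target
CpG. The background distribution is the same statistic computed between two
*resampled* sets: a query surrogate drawn uniformly without replacement from
the query-side captured-CpG pool and a target surrogate drawn from the
target-side pool, sizes matched to the real sets. Resampling both categories
keeps the two distance samples independent; reusing the real query set on
both sides pairs the samples and demonstrably miscalibrates the rank-sum
test. Density mode applies a Wilcoxon rank-sum test (normal approximation
with tie correction when ties are present -- zero distances tie often);
binned mode applies a one-tailed Fisher test per distance bin.

A known limitation: nearest-neighbor distances within one sample are
positively correlated through the shared target draw, so the rank-sum p is
only asymptotically calibrated, with anti-conservatism on the order of
n_query/n_target. The calibration property test therefore runs in the regime
the test is used in -- a few hundred query CpGs against a pool of thousands
(300 vs 3000 from a 50,000-site background on 10 Mb). With comparable set
sizes, p-values near the threshold should be interpreted cautiously.

## Synthetic data: the stated world

The simulator emulates the study design end to end: two families with
distinct mutations (A: 2 controls + 3 patients; C: 2 controls + 2 patients)
plus one unrelated donor control; a 2 x 5 Mb toy genome carrying 50,000 CpG
sites placed as a mixture of uniform background and Gamma-spaced clustered
islands (uniform placement would make the proximity statistics trivially
null); coverage ~ Poisson(30) per site, split binomially across the two
strands of each CpG dinucleotide so destranding is exercised; baseline
methylation ~ Beta(0.4, 0.4), the bimodal methylome. Planted DMRs (defaults
100 family-A, 100 family-C, 50 shared) shift patient rates by 40 percent
points; their baselines are drawn intermediate (0.10-0.50 for
hypermethylation, 0.50-0.90 for hypo) both to keep shifted rates in [0, 1]
and because the largest real differences occur at intermediate methylation.
Small per-family baseline offsets (SD 0.03 at 5% of sites) reproduce
genome-wide clustering by family. Companion files -- gene models, enhancer
and histone tracks covering a fraction of planted DMRs, LAD tracks arranged
so DMR-associated genes fall near gains of LAD, and DEG tables whose fold
changes oppose the planted methylation sign with probability rho = 0.65 --
are generated consistently with the planted truth. All randomness flows from
a single seed; equal seeds give byte-identical files.

What the generator does *not* emulate: read-level bisulfite conversion
errors, coverage biases of MspI digestion, overdispersion beyond binomial
sampling, sex chromosomes, and correlated methylation between neighboring
CpGs outside planted spans. A green recovery test therefore establishes that
the pipeline recovers the planted effect structure under binomial noise at
realistic coverage -- not that it is robust to every artifact of real RRBS.

### How recovery is scored

Recall/precision use >= 50% reciprocal overlap between called tiles and
planted spans, computed on the union of the two family-run tile sets. The
pooled run is excluded from this score deliberately: a family-specific
effect of 40 points appears diluted to 24 points (3/5 or 2/4 of samples) in
the pooled comparison -- below the 30-point cutoff -- so the pooled run's
occasional single-CpG fragments over planted family DMRs are partial true
detections rather than false positives, and counting them against precision
would mismeasure the generator's own design. Classification accuracy is
scored on classified tiles matched to truth.

## Numerical and reproducibility choices

* BH q-values; binomial LRT with the 0·log 0 = 0 convention and the
  statistic floored at 0.
* `closest` ties resolve to the smaller start, including the bookended-vs-
  overlapping tie at distance 0.
* Zero-length intervals are rejected at parse time; malformed methylation
  call lines are reported with their line numbers.
* The pipeline writes a JSON manifest per stage (parameters, seed, md5 of
  inputs and outputs, package version, no timestamps, paths relative to the
  output directory), so identical runs are byte-identical and unchanged
  stages are skipped.
* CLI exit codes: 0 ok, 2 config, 3 dependency, 4 data.

## Known limitations

No overdispersion correction or covariate adjustment in the per-CpG test; no
fixed-window DMR mode; no tabix-indexed access (whole tracks are held in
memory -- appropriate for RRBS-scale site counts); the rank-sum calibration
caveat above; GREAT's association rule is implemented but not its binomial
domain statistics.
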