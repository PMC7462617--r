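---
title: "Methods: joint chromatin-accessibility and expression analysis of two sorted populations"
author: "atacouple"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint chromatin-accessibility and expression analysis of two sorted populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacouple)
```

# Scope

`atacouple` compares two FACS-sorted cell populations — called `A` and `B`
throughout, modelled on GFP+ (posterior second heart field) versus Tomato+
(anterior second heart field / *Mef2c*-lineage) cardiac progenitors — that
have been profiled with both ATAC-seq and RNA-seq. It covers the analysis
downstream of alignment, peak calling and read counting:

* merging replicate narrowPeak sets into consensus peaks and classifying
  pooled peaks as shared or population-exclusive;
* quantitative differential accessibility and differential expression with
  a moderated negative binomial Wald test;
* an expressed/not-expressed call per gene per population against a
  detection threshold estimated from intergenic background windows;
* nearest-TSS peak annotation and the joint accessibility–expression
  coupling classification of each peak;
* PWM scanning of summit-centred sequences and enrichment of single
  motifs and order-3 motif combinations against random genomic background.

A bundled synthetic-data generator produces complete datasets with known
ground truth; every statistical claim in the test suite is checked against
either an independent oracle or that truth.

# Data model and conventions

All genomic intervals are 0-based half-open (BED convention) everywhere in
the package; conversion to the 1-based closed convention of `GRanges`
happens only inside the interval-plumbing helpers. A narrowPeak summit is
stored as an offset from the peak start; `-1` means unknown, in which case
the interval midpoint (floored) acts as the summit — merged consensus
peaks always use the midpoint, since merging discards caller summits.
Gene models are a flat table (`gene_id`, `chrom`, `start`, `end`,
`strand`); the TSS is `start` on `+` and `end - 1` on `-`. Count tables
are integer matrices (features × samples) with an `A`/`B` label per
sample.

# Normalization and the detection threshold

Size factors are median-of-ratios: per sample, the median over
all-positive genes of the ratio to the gene's geometric mean across
samples. Factors are scale-equivariant and invariant to gene order; a
table without any all-positive gene is an error rather than a silent
fallback.

The detection threshold asks how much signal a "silent" genomic region
produces. Counts in 5 kb intergenic windows are normalized with the gene
size factors, transformed as `log2(normalized count + 1)`, and the
nearest-rank 95th percentile (`ceiling(0.95 n)`-th sorted value) is taken
per sample. Nearest-rank was chosen over interpolating definitions
because it is deterministic, exact in tests, and insensitive to ties. The
pooled threshold is the maximum over samples — the conservative choice: a
gene must beat the noisiest library's background. A gene is called
expressed in a population when the mean over that population's replicates
of `log2(normalized count + 1)` strictly exceeds the threshold; a gene
exactly at the threshold is not expressed. The Venn partition of the two
expressed sets (shared / specific to A / specific to B) is the
expression-side summary.

Genes with zero counts in every sample are removed before analysis.
Removing genes "per sample" would break the rectangular count matrix, so
the all-sample rule is used; genes with any non-zero entry are kept.

Intergenic windows and gene counts are compared on the same
normalized-count scale without length normalization; this treats a 5 kb
window as a pseudo-gene, which is an approximation the detection
threshold inherits from its inputs.

# The moderated NB Wald test

Both differential branches use one engine, `nb_wald_test()`. Counts are
modelled as negative binomial with per-sample size factors `s_j`,
population means `mu_A`, `mu_B` and a per-feature dispersion `alpha`
(variance `mu + alpha mu^2`).

Estimation is deliberately closed-form:

* group means are averages of normalized counts;
* the raw dispersion is method-of-moments,
  `(v_within - mu * mean(1/s)) / mu^2`, with `v_within` the pooled
  within-group variance of normalized counts;
* the across-feature trend is the **unclamped** mean of the raw estimates
  over features with `mu > 1`. Raw moment estimates are right-skewed and
  often negative at small replicate numbers; clamping or trimming before
  averaging biases the trend low, which in turn inflates type-I error.
  The unclamped mean is approximately unbiased;
* the working dispersion shrinks the (floored) gene-wise estimate halfway
  toward the trend: `0.5 * max(raw, 1e-8) + 0.5 * trend`;
* the Wald statistic is `log2(mu_A / mu_B) / se`, with the delta-method
  standard error of each group's log2 mean, referred to a t distribution
  with `df = residual df + prior df`. The prior df (default twice the
  residual df, i.e. df = 12 at 3 versus 3) represents the information the
  trend contributes to the shrunk dispersion. The default was fixed once
  by null-calibration simulation: across seeds, null p-values are
  indistinguishable from uniform by a KS test, the rejection rate at 0.05
  is near nominal, and power at a planted two-fold log2 shift with
  dispersion 0.1 exceeds 0.8 at BH FDR 0.10. A standard-normal reference
  was visibly anticonservative at three replicates and `t(n-2)` had
  essentially no power.

Features where one population's mean is zero report a signed-infinite
log2 fold change; the p-value is computed with the zero mean replaced by
0.5 normalized counts (the minimal detectable level) and the row is
flagged `zero_group` rather than dropped. Features that are zero
everywhere are flagged `all_zero` and excluded from testing (NA p).

BH adjustment is applied over tested features. Differential expression
reports two call sets used by different parts of the analysis: adjusted
p < 0.05, and |log2fc| >= 1 with FDR <= 0.01. Differential accessibility
defaults to FDR <= 0.10 with no fold filter (the fold filter is exposed
as an option, default off, since the primary threshold is the FDR).
Fold changes are always oriented A over B.

# Consensus peaks, classification and annotation

Replicate peaks are merged by >= 1 bp interval overlap; a merged peak is
kept when peaks from at least `min_support = 2` replicates overlap it.
This support filter is the package's reproducibility criterion; a full
rank-consistency (IDR-style) filter is out of scope and can be applied
upstream, feeding its surviving peaks in as replicates. Classification
builds the pooled union of the two populations' consensus sets: a pooled
peak overlapped by both is `shared`, otherwise exclusive to the
population that covers it. Counts always partition the pooled total — an
invariant asserted at run time.

Peak-to-gene assignment is nearest TSS by absolute distance from the
summit, within a ±150 kb window; peaks with no TSS in the window stay
unassigned. Ties (equidistant TSSs) break toward the lexicographically
smaller gene id so that results are reproducible across platforms. Each
peak is also categorised: `tss_proximal` within 1 kb of the chosen TSS,
else `genic` if the summit falls in any gene body, else `intergenic`.
TSS over-representation between the A-exclusive and B-exclusive classes
is a one-sided Fisher test on the 2×2 proximal/other table.

Read counting over pooled peaks accepts either precomputed per-locus
counts (transferred to pooled peaks by overlap) or per-sample fragment
lists counted by fragment midpoint — the midpoint rule assigns each
fragment to at most one peak.

# Coupling

Each assigned peak is classified at a common FDR threshold (default 0.1
in both assays): `concordant_A` when both the accessibility and the
nearest gene's expression change are significant and positive (A over
B), `concordant_B` when both are significant and negative, `discordant`
when both are significant with strictly opposite signs, otherwise
`not_significant`; peaks without a gene in the window are `unassigned`.
A log ratio of exactly zero carries no direction and is never called
concordant or discordant. A nearest gene that was filtered before
differential testing (all-zero) leaves its peak unassigned, keeping the
"unassigned iff no usable gene" invariant. Raising the FDR threshold can
only promote peaks out of `not_significant`, never demote them — a
monotonicity property under test.

# Motif scanning and combination enrichment

PWMs come from JASPAR-style PFM files and are regularized with a
pseudocount (`(c + pc) / (sum c + 4 pc)` per column). Scanning scores
`sum_i log2(p_i[base] / background[base])` at every offset on both
strands; an offset is a hit when the score reaches a configurable
fraction (default 0.8) of the maximum attainable score. Ambiguous bases
score `-Inf` at their column, so windows containing N cannot reach any
positive threshold. The scanner is validated against exhaustive
per-offset scoring and an exact reverse-complement symmetry property.

Enrichment compares summit-centred sequences of A-exclusive peaks
(±200 bp, i.e. 400 bp windows) against random background windows sampled
uniformly from the genome (default 20,000 × 400 bp; windows with more
than 10% ambiguous bases are resampled; GC matching is available as an
option, default off, since plain random sampling is the primary design).
Presence — at least one hit in the sequence — rather than hit counts
defines the 2×2 table per motif, and the test is one-sided (greater)
Fisher, BH-adjusted.

Order-3 combinations enumerate all C(n, 3) unordered motif triples. A
combination is present in a sequence when one hit of each motif can be
chosen such that the union of their footprints spans at most 500 bp.
With 400 bp summit windows this reduces to co-presence — the general
span rule matters only for longer sequences, and the equivalence at
span >= sequence length is covered by a test. Scanning is performed once
per (sequence, motif); combination presence is computed from the cached
hits, never by rescanning.

On exact tests and calibration: Fisher's exact test conditions on the
table margins and its p-values are discrete and conservative —
`P(p <= a) <= a`, with strict inequality almost everywhere. The null
calibration experiment in the test suite therefore checks level control
(the rate of p < 0.05 against the binomial interval at the number of
combinations) and reports a pooled KS uniformity statistic with the
caveat that a KS test against the continuous uniform rejects any exact
conditional test at large pooled sample sizes; the observed deviation is
one-sided in the conservative direction, which does not invalidate the
enrichment ranking or FDR control.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of the study's
deposited data: two populations × 3 replicates, peak sets with
shared/exclusive structure, NB counts, coupled peak–gene pairs, and
planted motif triples. Its defaults are the study conditions and are not
tuned per experiment:

* peak class fractions 0.94 / 0.035 / 0.025 (shared / A-exclusive /
  B-exclusive), matching the reported sharing structure;
* 3 replicates per population, NB dispersion 0.1, baseline log2 means
  uniform on [5, 9], library-size factors log-uniform on [0.5, 2];
* planted |log2 fold changes| of 2 in 10% of genes, accessibility shifts
  of ±2 for exclusive peaks (split symmetrically across populations so
  the base mean is shift-invariant);
* 15% / 5% of genes specific to A / B (silent in the other population at
  a fixed low mean of 2 normalized counts, i.e. ≥ 4 log2 units below the
  expressed range);
* intergenic windows at NB mean 2;
* peak width 400 bp with per-replicate boundary jitter up to 10% of the
  width; a planted HOX/PBX/MEIS-like motif triple written into 60% of
  A-exclusive summit windows within a 300 bp span.

Placement uses a slot layout: the genome is divided into slots of about
3 kb, each peak locus owns one slot, and its gene's TSS (when the locus
owns a gene) is placed 100–1000 bp from the summit inside the same slot.
This models promoter-proximal accessibility and makes nearest-TSS
assignment unambiguous by construction, which is what lets the coupling
truth table be exact. Loci that own no gene are chosen uniformly so that
gene-less regions do not cluster. One global seed fans out to fixed
per-stage child seeds, so each stage is individually reproducible and
the whole dataset is byte-identical under a fixed seed.

The built-in motif set has five high-information and three degenerate
positions per 8-mer, giving per-window occurrence probabilities around
0.25–0.5 at the default scan threshold — high enough that co-occurrence
tables are informative, low enough that a planted triple dominates.

What the generator does **not** emulate: read-level noise (Tn5 bias,
fragment-length structure, mappability), correlated dispersion trends,
GC effects on counts, overlapping genes or peaks, and any real genome
sequence composition beyond uniform GC. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not performance on any particular real dataset.

# Problem sizes used in validation

The test suite and the acceptance script run on scaled-down but
structurally complete instances chosen as the package's own validation
sizes: differential testing at 2,000 genes / 5,000 peaks (3 vs 3),
planted-combination recovery on a 2 Mb genome with 300 A-exclusive
windows and 2,000 background sequences, null calibration over 50 runs of
300 + 1,000 windows, and an end-to-end pipeline at 2,000 peaks / 1,500
genes with the full 20,000-sequence background. Each validation quantity
is recomputed from scratch at run time.

# Known limitations

* The NB engine is a documented approximation, not a re-implementation
  of DESeq2/edgeR numerics: no Cook's-distance outlier handling, no
  mean-dispersion trend curve, no fold-change shrinkage. Acceptance is
  against synthetic truth, not against another tool's output.
* The detection threshold treats intergenic windows and genes on the
  same normalized scale without length correction.
* Coupling assigns exactly one gene per peak (nearest TSS); multi-gene
  regulation and enhancer–promoter loops are out of scope.
* The combination test reports exact Fisher p-values, which are
  conservative; ranking and FDR control are unaffected, but the raw
  p-value distribution under the null is discrete, not uniform.
* `run_pipeline()` performs the motif stage only when at least one
  A-exclusive pooled peak exists.
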