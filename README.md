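# atacouple

Joint chromatin-accessibility and gene-expression analysis for two
FACS-sorted cell populations profiled by ATAC-seq and RNA-seq — the
comparison design used to contrast cardiac progenitor subpopulations of
the second heart field (a GFP-labelled posterior population versus a
Tomato-labelled anterior/*Mef2c*-lineage population), implemented as a
reusable, fully tested R pipeline.

## What it computes

Given per-replicate narrowPeak files, gene/peak/intergenic count tables,
a genome FASTA, a gene table and a PWM set, the pipeline produces:

* **Consensus peaks and sharing structure** — replicate peaks merged on
  ≥ 1 bp overlap with a ≥ 2-replicate support filter; pooled peaks
  classified `shared` / `exclusive_A` / `exclusive_B` by presence in the
  two populations' consensus sets (the qualitative pie-chart analysis).
* **Differential accessibility and expression** — a moderated negative
  binomial Wald test on size-factor-normalized counts. Per feature *f*
  with population means μ_A, μ_B and dispersion α (Var = μ + αμ²):
  gene-wise method-of-moments dispersion shrunk 50/50 toward the
  across-feature trend, then W = log2(μ̂_A/μ̂_B) / SE referred to a
  moderated-df t distribution, BH-adjusted. Accessibility is called at
  FDR ≤ 0.10; expression at adjusted p < 0.05 and at |log2FC| ≥ 1 with
  FDR ≤ 0.01.
* **Expressed-gene partition** — a detection threshold set at the
  nearest-rank 95th percentile of log2(normalized count + 1) over 5 kb
  intergenic windows; genes called expressed per population and
  partitioned into shared / A-specific / B-specific sets.
* **Peak–gene coupling** — each pooled peak annotated with its nearest
  TSS within ±150 kb of the summit and classified by joint significance
  at FDR < 0.1 in both assays: concordant (same direction in
  accessibility and expression), discordant, not significant, or
  unassigned.
* **Motif and motif-combination enrichment** — summit-centred ±200 bp
  sequences of A-exclusive peaks scanned with PWMs (log2-odds, both
  strands, threshold 0.8 × max score) against 20,000 random 400 bp
  genomic windows; per-sequence presence tested with one-sided Fisher's
  exact tests for single motifs and for all order-3 motif combinations
  co-occurring within 500 bp, BH-adjusted.

A synthetic-data generator (`simulate_dataset()`) emits complete datasets
with ground-truth tables (peak classes, planted fold changes, coupled
peak–gene pairs, planted motif triples) and drives the validation suite.

## Worked example

```r
library(atacouple)

cfg <- sim_config(seed = 42)                       # study-scale defaults
dir <- file.path(tempdir(), "shf_demo")
ds  <- simulate_dataset(cfg, dir)                  # writes the dataset directory

pc  <- pipeline_config(dataset_dir = dir, background_n = 2000, seed = 42)
res <- run_pipeline(pc)

res$classification
#> peak classification: 2000 pooled peaks (94.0% shared, 3.5% exclusive A, 2.5% exclusive B)
res$threshold
#> detection threshold: 3.0714 log2(normalized count + 1) (p95 over 1000 windows)
res$partition
#> expression partition: 1200 shared, 225 specific to A, 75 specific to B (threshold 3.071)
sum(res$de$sig_adj_p); sum(res$da$significant)
#> [1] 450
#> [1] 115
coupling_summary(res$coupling)
#>    concordant_A    concordant_B      discordant not_significant      unassigned
#>              25              20               9            1946               0
head(res$motif$combinations[, c("motif_1", "motif_2", "motif_3", "k_peak", "k_bg", "fdr")], 3)
#>     motif_1   motif_2  motif_3 k_peak k_bg          fdr
#> 1  HOX_like MEIS_like PBX_like     43  130 1.584268e-28
#> 2  HOX_like MEIS_like     TF11     25  120 8.929337e-11
#> 3 MEIS_like  PBX_like     TF11     24  125 9.410791e-10
```

Reading the output: the pooled peak set reproduces the planted sharing
structure (94% of open regions common to both populations); 450 genes are
differentially expressed at adjusted p < 0.05 and 115 peaks differentially
accessible at FDR ≤ 0.10; 25 peaks are concordantly more open and more
expressed in population A (20 in B) — the machine-readable analogue of
the coloured points in an accessibility-versus-expression scatter; and
the planted HOX/PBX/MEIS-like motif triple ranks first among all 220
order-3 combinations.

A thin command-line front end is included:

```sh
Rscript inst/scripts/atacouple-pipeline.R simulate --out data_dir --seed 1
Rscript inst/scripts/atacouple-pipeline.R run --dataset data_dir --out results_dir --seed 1
```

See `vignettes/atacouple-methods.Rmd` for the model, parameter and
calibration details.

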