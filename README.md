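# sckit

Benchmarking metrics for single-cell RNA-seq library-preparation kits.

Commercial scRNA-seq kits differ in how efficiently they turn sequencing
reads into usable molecular counts, how quickly gene detection saturates
with depth, how stably they measure gene expression, how faithfully they
recover the cell-type composition of the input sample, and how well the
resulting data separate cell types. `sckit` implements a full evaluation
pipeline for these questions, operating on UMI count matrices and
aggregated read-level summaries — no vendor pipeline or sequence data
required — plus a synthetic multi-kit data generator so every stage can be
exercised and tested end-to-end without downloading anything. It is aimed
at groups comparing kits (or protocol variants) on a common sample.

## The metrics

**Read accounting.** Reads are split into three categories: A (uniquely
mapped, tagged with a called cell's barcode), B (mapped, non-cell barcode)
and C (everything else). Read utilization is A/total; UMI recovery is
total UMIs / total reads. Two cell callers are included: a threshold
caller with five sensitivity levels

```
T_i = M * 10^-(0.5 + 0.25 L_i),   L_i = 1..5
```

where `M` is the count of the first ranked barcode whose drop from its
predecessor is at most 10%, and a fixed-count caller that returns exactly
the top-n barcodes.

**Depth saturation.** Count matrices are downsampled across a
reads-per-cell grid by per-molecule binomial thinning (a molecule with
`r` reads survives thinning at rate `p` with probability `1-(1-p)^r`),
and the median genes/UMIs per cell follow a Michaelis–Menten curve

```
nu = Vmax * S / (Km + S)
```

with `S` the read depth, `Vmax` the saturation level, and `Km` the depth
of half-maximal detection. Kits are grouped into sensitivity tiers by
Ward-clustering 34 equidistant points along the fitted curves.

**Expression stability.** Per-gene dropout (fraction of cells with zero
CPM) decays with pseudobulk expression `x` as `exp(-b x)`; the
half-maximal dropout expression is `GD50 = ln(2)/b`. Gene specificity is
an entropy statistic `S_i = (1/t) Σ_j (p_ij/p_i) log2(p_ij/p_i)` in
`[0, log2 t]`; its distribution peak is located by Gaussian KDE. Both are
bootstrapped on paired cell resamples.

**Composition and discrimination.** Consensus annotation from two label
vectors with majority reclassification on an overclustering (≥60%, never
"Unassigned"); bootstrapped cell-type proportions compared to a reference
distribution via mean absolute difference and cophenetic distance in a
joint Ward dendrogram; Leiden resolution scan to the label-matched
clustering scored by ARI/AMI (plus class-balanced variants), silhouette
width and cumulative variance ratio; one-vs-rest Wilcoxon differential
expression (log2FC > 2, BH-adjusted p < 0.05, min 10 cells per type).

**Summary.** Per-category tiers (fixed rules, KDE natural breaks, or Ward
clustering) and a min-max-normalized feature-score matrix on [0, 1], with
inverted orientation for metrics whose optimum is small.

## Worked example

Simulate a high-performance and a low-performance kit profile on the same
PBMC-like composition and run the whole pipeline:

```r
library(sckit)

reference <- proportion_table("CyTOF", c(
  "B cells" = 0.12, "CD14+ monocytes" = 0.25, "CD4+ T cells" = 0.35,
  "NK cells" = 0.15, "CD8+ T cells" = 0.13))

profiles <- list(
  kit_profile("good", capture_efficiency = 0.9, dropout_decay_b = 0.012,
              mt_fraction = 0.02, rp_fraction = 0.15,
              read_category_probs = c(0.8, 0.1, 0.1), dispersion = 0.2),
  kit_profile("bad", capture_efficiency = 0.35, dropout_decay_b = 0.008,
              mt_fraction = 0.12, rp_fraction = 0.25,
              read_category_probs = c(0.4, 0.25, 0.35),
              celltype_bias = c("CD14+ monocytes" = 0.4), dispersion = 0.5))

panel <- simulate_kit_panel(profiles, reference, n_cells = 800,
                            n_genes = 600, seed = 1)
res <- run_kit_benchmark(panel, reference, target_cells = 800,
                         depth_grid = seq(1000, 16000, by = 1000),
                         seed = 1001)
res$metric_table
```

```
<metric_table> 2 kits x 11 metrics (inverted: Mito QC, CyTOF Similarity, Gene Expression Stability)
     Read Utilization Cell Yield (% of Target) Gene Saturation UMI Saturation
good              0.8                       98         573.753      24844.755
bad               0.4                       98         322.700       5436.103
     Genes (per Cell) UMIs (per Cell) Mito QC Gene Expression Stability
good            543.0         10811.0    1.90                    78.677
bad             370.5          2789.5   11.28                   351.810
     CyTOF Similarity Differential Expression Cluster Discrimination
good            0.023                    23.6                    0.9
bad             0.165                    23.8                    1.0
```

Reading the rows: the good kit uses 80% of its reads (vs 40%), detects
more genes and UMIs per cell at every depth (saturation Vmax 574 vs 323
genes), keeps mitochondrial contamination low (1.9% vs 11.3%), measures
expression more stably (GD50 79 vs 352 CPM — dropout for the bad kit
persists to much higher expression), and sits much closer to the
reference composition (cophenetic distance 0.023 vs 0.165; the bad kit's
planted monocyte depletion is what pushes it away). Individual stage
results live in `res$per_kit`, e.g. the saturation fit and the paired
stability bootstrap:

```
<mm_fit> genes saturation (good)
  Vmax = 573.753, Km = 1058.82 reads/cell, residual norm = 11.64
<stability_boot> good: 30 iterations of 500 cells
  mean GD50 = 78.677 CPM (95% CI 77.991-79.46)
  mean specificity peak = 0.22596 (95% CI 0.22171-0.22984)
```

`res$feature_scores` is the final kits × metrics score matrix in [0, 1]
(1 = optimal per metric after orientation); here the good kit dominates
9 of the 11 columns.

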