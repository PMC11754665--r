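---
title: "Methods: benchmarking scRNA-seq kits with sckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking scRNA-seq kits with sckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sckit)
```

`sckit` scores single-cell RNA-seq library-preparation kits on a common
sample along five axes: read economy, depth saturation, expression
stability, compositional fidelity, and cluster discrimination. This
vignette describes each model and procedure, the parameters that matter,
the synthetic-data generator the tests rely on, and the numerical and
design choices made where more than one reasonable option existed.

## Read accounting and cell calling

Reads are partitioned into category A (uniquely mapped and tagged with a
barcode that a cell caller accepted), B (mapped but carrying a non-cell
barcode) and C (everything else: unmapped, untagged, duplicates).
`read_utilization()` reports the three fractions; conservation
(A + B + C = total) is enforced by the `read_assignment_table`
constructor itself, so malformed tables cannot enter the pipeline.
`umi_recovery()` is total UMIs over total reads; values above 1 are
reported unclamped with a warning since they always indicate inconsistent
inputs rather than a legitimate state.

Two cell callers are implemented. The threshold caller derives an anchor
count `M` by scanning the ranked barcodes from rank 2 down and taking the
first count whose relative drop from its predecessor, `(prev - cur)/prev`,
is at most 10%. Three readings were possible; we start at rank 2 because
rank 1 has no predecessor, use a relative drop because an absolute one
would not be scale-free, and treat a drop of exactly 10% as qualifying
(the rule excludes drops of *more than* 10%). On profiles where no rank
qualifies (e.g. strictly geometric decay) the last ranked count is
returned with a warning rather than failing, so batch runs survive
degenerate profiles. The five thresholds are
`T_i = M * 10^-(0.5 + 0.25 L_i)`, kept real-valued; a barcode exactly at
threshold is called (inclusive comparison — the threshold is defined as
the count required *to be called*). Ranking ties are broken
lexicographically by barcode so rankings, and therefore the fixed-count
caller's output, are stable and reproducible.

## Depth saturation

Resequencing at lower depth is emulated at the count level: each read
survives independently with probability `p = target/current` depth, and a
molecule is retained if at least one of its reads survives, i.e. with
probability `1 - (1-p)^r` for `r` reads per molecule. This is applied as
binomial thinning of the UMI counts and is statistically equivalent to
read-level downsampling for per-cell gene and UMI medians, at a tiny
fraction of the cost. When read multiplicities are unknown the UMI counts
themselves are thinned (`reads_per_molecule = NULL`); this is optimistic
about saturation — it ignores duplicate reads — and is documented as
such.

Median genes and UMIs per cell across the depth grid (default 2000 to
30000 reads per cell in steps of 2000; all 15 grid points are emitted)
are fitted with the Michaelis–Menten curve `nu = Vmax*S/(Km+S)` by
bounded Levenberg–Marquardt least squares, initialized at
`Vmax0 = max(nu)` and `Km0 = median(S)`. The initialization matters
little on clean series but keeps the optimizer away from the degenerate
ridge `Vmax, Km -> Inf` that a perfectly linear series (UMIs far from
saturation) produces; on such series the reported parameters are large
and the residual norm small, which downstream tier clustering handles
gracefully because curves are only ever evaluated inside the observed
depth range. Sensitivity tiers Ward-cluster (Euclidean distance) each
kit's curve evaluated at 34 equidistant depths spanning the common grid —
no extrapolation — and number tiers by descending mean curve value. The
tier count is a user parameter (typically 3 for genes, 2 for UMIs); the
tool does not auto-select it.

## Preprocessing and QC

`preprocess()` applies, in a fixed order that is part of the contract:
cells with fewer than 5 detected genes are removed; cells with doublet
score ≥ 0.25 are removed (the threshold is inclusive — a score *at* the
threshold is treated as a doublet, the reading most consistent with a
removal threshold); the matrix is randomly subsampled without replacement
to a uniform cell count (study-scale default 7750), with datasets smaller
than the target kept whole and flagged; genes detected in fewer than 3
cells are removed last, so gene prevalence is evaluated on exactly the
cells that survive. Permuting these steps changes the result, which the
test suite pins with a fixture of known intermediate shapes.

QC metrics are per-cell gene counts, UMI counts, and the percentage of
counts in mitochondrial (`MT-` prefix) and ribosomal-protein
(`RPS`/`RPL`) genes. Cross-kit comparisons of these per-cell
distributions use the Kruskal–Wallis omnibus test followed by Dunn's
pairwise post-hoc tests with tie correction and Bonferroni adjustment
over all pairs. Dunn's test is implemented in the package (large-sample
normal approximation, the standard formulation) because no installed
package provides it; it reduces to a single unadjusted comparison for two
groups, which the tests assert.

## Dropout decay and gene specificity

Within each bootstrap iteration, cells are resampled with replacement,
CPM-normalized (each cell scaled to one million), and two statistics are
computed from the *same* subsample so they can be compared downstream as
a pair: the dropout decay and the specificity-density peak. Dropout for a
gene is the fraction of cells with zero CPM; it is modeled against
pseudobulk expression `x` (mean CPM) as `exp(-b x)` with the scale fixed
at 1 — dropout is complete at zero expression — and `b` bounded in
[0, 0.05] per CPM, with a seeded uniform random start in that interval.
`GD50 = ln(2)/b` is the expression at which half the cells drop out;
`GD50 * b = ln 2` holds identically and is asserted. Genes are restricted
to the intersection detected in all kits before bootstrapping so kits are
compared on a common panel. Zero-dropout genes enter the fit as ordinary
data points (unweighted least squares). When `b` is driven to its upper
bound the fit warns; when `b = 0` GD50 is undefined and reported missing.

Gene specificity is `S_i = (1/t) Σ_j (p_ij/p_i) log2(p_ij/p_i)` with
`p_ij` the CPM proportion of gene `i` in cell `j` and `p_i` its mean.
Zero-expression cells contribute 0 (the `z log z` limit), giving the
exact landmarks the tests pin: 0 for a uniformly expressed gene,
`log2 t` for a single-cell gene, 1 for a gene equally expressed in 2 of
4 cells. Note that after CPM normalization the score is identical whether
`p_ij` is read as the gene's share of its cell or the cell's share of the
gene, since the two differ by a gene-constant factor that cancels in the
ratio. The distribution peak is the argmax of a Gaussian KDE evaluated on
a 512-point grid over the observed range, with the Scott bandwidth
`sd * n^(-1/5)`; we use that exact rule (rather than R's 1.06-factor,
IQR-capped default) because natural-break detection on small tightly
clustered vectors is sensitive to the bandwidth constant, and the Scott
rule is the default of the density estimator this procedure is built
around.

## Pseudobulk, PCA and feature selection

Pseudobulk expression is mean `log1p(CPM)` across cells; it is invariant
to cell order and equals the single-cell value for one cell. Cross-sample
PCA restricts to genes with nonzero pseudobulk in every sample, centers
each gene across samples, and does not scale to unit variance: scaling is
left off because pseudobulk values are already on a common log scale and
scaling would inflate near-constant genes. `covariate_correlation()` is a
plain Pearson correlation for relating loadings to gene covariates
(length, GC) or embeddings to sample covariates.

Informative features are ranked by per-gene binomial deviance under a
constant-proportion null with cell-total size factors: with cell totals
`n_i`, gene counts `y_i`, and `pi = Σy/Σn`, the deviance is
`2 Σ_i [ y_i log(y_i/(n_i pi)) + (n_i - y_i) log((n_i - y_i)/(n_i (1 - pi))) ]`
with `0 log 0 = 0`. A gene exactly proportional to cell totals scores 0;
overdispersed, cell-type-structured genes score high. For multiple
samples, deviance is computed per sample and genes are ranked by their
median rank across samples.

## Annotation and composition

Consensus labels keep a cell's label where two annotators agree and mark
disagreements "Unassigned". Reclassification on an overclustering assigns
a cluster's modal consensus label to all its cells iff that label covers
at least 60% of the cluster (inclusive) and is not "Unassigned"; modal
ties never qualify — the conservative reading of "at least 60% share the
same label". The operation is idempotent, which is asserted as a
property. The two-stage coarse-split-then-overcluster workflow is
expressed through configuration (any cluster vector can be supplied)
rather than hard-coded resolutions, since useful resolutions are
data-dependent.

Cell-type proportions are bootstrapped by resampling cells with
replacement (study-scale defaults: 500 draws of 7882 cells), dropping
excluded labels (defaults: Megakaryocytes and Unassigned, the labels
absent from a cytometry reference) and renormalizing. Fidelity to the
reference is scored two ways: per-type mean absolute difference of the
bootstrapped proportions, and the cophenetic distance between each kit's
leaf and the reference leaf in a joint Ward dendrogram over proportion
vectors. The cophenetic construction is this package's operationalization
of a "reference similarity" score from a dendrogram; it is the most
direct reading available but other constructions exist, so it is
documented rather than claimed canonical.

## Discrimination scores

`optimal_resolution_scan()` runs Leiden community detection (modularity
objective, shared-nearest-neighbor graph with exact k-nearest neighbours
from the embedding) across a resolution grid (default 0.02–1.00 in steps
of 0.02) and selects the lowest resolution whose cluster count is closest
to the number of distinct labels, ties resolving to the lower resolution.
ARI and AMI are implemented from the contingency table, AMI with the
exact hypergeometric expected-MI correction and arithmetic-mean
normalization (the common library default); an independent package
implementation of ARI serves as a cross-check in the tests. The balanced
variants reweight each true class (row) to equal mass, preserving the
grand total, and then apply the same formulas with the continuous pair
count `x(x-1)/2`; for AMI the rebalanced table is rounded
total-preservingly because the expected-MI term requires integer
marginals. By construction the balanced variants equal the plain ones
when classes are exactly equal-sized, which is the property the tests
pin; the exact internals of other balanced-index implementations may
differ. ASW is the mean silhouette width of the labels on the embedding
mapped to [0, 1] via `(s+1)/2`; CVR is the summed variance fraction of
the embedding's first 10 PCs.

One-vs-rest differential expression subsamples to a uniform cell count
(study default 3457), drops types below 10 cells, and tests each gene
with a two-sided Wilcoxon rank-sum test (vectorized normal approximation
with tie correction — the convention of single-cell rank-test
implementations; the exact test agrees on small instances and is used as
the oracle in the tests). Significance requires log2 fold change above 2
*and* BH-adjusted p below 0.05, with adjustment within each cell type's
gene family. The fold change is computed on `expm1` of mean `log1p`
normalized expression with a small pseudocount, matching the convention
of the rank-test implementation this mirrors. DEG counts are z-scored per
cell type across kits using the sample standard deviation; a type with no
across-kit variation scores 0 for every kit.

## Tiers and feature scores

Rule-based categories use fixed printed thresholds: cell recovery within
±20% of target (inclusive at the boundary — "within" naturally includes
it) is Tier 1; maximum yield >20000 / 10000–20000 / <10000; protocol
time <8.5 h / 8.5–16 h / >16 h; mitochondrial fraction ~0% / <10% /
>10%; ribosomal fraction ~0% / otherwise. "Approximately 0%" has no
printed cutoff and is operationalized as below 0.5% (configurable).
One-dimensional metrics with no printed rule get natural-break tiers:
Gaussian KDE (Scott bandwidth, 512-point grid padded by one bandwidth)
with boundaries at interior density minima, optionally after `log1p` for
cost-like metrics; no interior minimum means one tier.
Multi-dimensional categories (e.g. genes and UMIs per cell jointly) are
Ward-clustered and cut at a user-chosen k. Feature scores min-max
normalize each metric across kits and invert metrics whose optimum is
small (protocol time, costs, mitochondrial QC, reference-composition
distance, GD50); a constant metric is undefined under min-max and is set
to the neutral 0.5 with a warning rather than an arbitrary 0 or 1.

## The synthetic-data generator

`simulate_counts()` draws each cell's type from the supplied proportions
reweighted by the kit's recovery bias, its library size from a Poisson
around `capture_efficiency * mean_umis_per_cell`, and its gene counts
from a gamma–Poisson (negative binomial) with a single kit-level
dispersion around cell-type mean profiles. The profiles are log-normal
over genes with a subset of marker genes boosted per type, drawn once per
run and shared across kits so cross-kit pseudobulk correlation is high by
construction. Mitochondrial and ribosomal gene mass is imposed exactly in
expectation. By default the library size is derived from the kit's
dropout decay parameter as `1e6 * dropout_decay_b`, because under Poisson
noise a library of `L` UMIs yields dropout `exp(-(L/1e6) * CPM)` — the
decay parameter is generative, not decorative; with overdispersion the
realized decay is no longer exactly exponential, so parameter-recovery
tests use zero dispersion. Read assignments are simulated as aggregate
multinomial category counts (every downstream statistic uses totals
only), rank profiles as two log-normal barcode populations whose scale
separation plants the knee, and annotator pairs as truth plus a small
uniform error for annotator 1 and a controlled agreement rate for
annotator 2.

What the generator does *not* emulate: ambient RNA contamination inside
called cells, batch chemistry effects beyond the profile parameters,
doublet expression profiles (only scores are attached), gene–gene
correlation structure, or sequence-level artifacts. Tests passing on
synthetic data therefore validate the statistical machinery and its
contracts, not kit rankings on real libraries.

## Problem sizes and defaults

Study-scale defaults (500 bootstrap draws of 7750/7882 cells, DE
subsample 3457, resolution grid to 1.0 in steps of 0.02) are the
documented defaults of the corresponding functions. The test suite and
the acceptance script run the same machinery at desk scale — panels of
800 cells × 600 genes, 20–100 bootstrap draws of 500–2000 cells, a
1000–16000 depth grid — sizes chosen so the full pipeline completes in
seconds while every statistic remains well inside its asymptotic regime
(binomial standard errors at these n are an order of magnitude below the
tolerances asserted).

## Known limitations

The balanced agreement indices are this package's pinned definition, not
a reimplementation of any specific library's internals. The cophenetic
similarity score depends on the whole kit set through the joint
dendrogram, so adding a kit can change other kits' scores. Direct UMI
thinning (without read multiplicities) overstates saturation. The Fluent
anchor scan's boundary behaviour (exactly 10% qualifies) follows the
rule's wording; instruments may differ. KDE natural breaks depend on the
bandwidth rule; with a handful of kits the Scott rule can merge close
groups.
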