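---
title: "Ordered promiscuous gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordered promiscuous gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pgemod)
```

## The question and the approach

Medullary thymic epithelial cells (mTEC) collectively express most of the
protein-coding genome — promiscuous gene expression (PGE) — to present
tissue-restricted antigens for tolerance induction, but each single cell
expresses only a few percent of the tissue-restricted genes (TRGs) at a
time. `pgemod` implements an analysis pipeline for deciding whether this
single-cell programme is stochastic (each cell samples TRGs
independently) or ordered (recurring co-expression modules): discover
gene modules with a weighted TF-IDF-style transform, score their
stability under subsampling, characterise their composition with Monte
Carlo statistics, check their reproducibility across mice, and test the
spatial arrangement of marker-positive mTEC in tissue sections against
even, random and clustered point processes. Every stage is exercised on
synthetic data with known planted structure, so parameter recovery — not
resemblance to any particular dataset — is the test of correctness.

## Quality control and normalisation

Cells are filtered by three median-absolute-deviation rules computed per
batch: total counts below median − 1·MAD, detected features below
median − 1·MAD, or mitochondrial fraction above median + 3·MAD. The MAD
uses the 1.4826 consistency constant and is applied on the raw scale.
Batches with fewer than 10 cells are passed through unfiltered with a
warning, because a MAD from a handful of cells is meaningless.
Normalisation scales every cell to the median pre-normalisation total
(size factor = cell total / median total); it conserves within-cell
proportions exactly. Deconvolution-style size factors are deliberately
out of scope.

Batch correction is a pluggable *embedding* contract, not a corrected
expression matrix: only the cell-graph construction consumes it, and the
GF-ICF transform is defined on the uncorrected normalised matrix. The
built-in default is PCA of log2(1 + counts) followed by per-batch mean
centring in PC space; an externally computed corrected embedding of
matching cell order can be substituted.

## Cell clustering

A shared-nearest-neighbour graph is built on the first 50 principal
components (k = 10 neighbours; edge weight = Jaccard index of the two
k-NN sets) and partitioned with Louvain modularity maximisation
(resolution 1). Sorted conditions are tested for cluster
enrichment/depletion by pairing, per mouse, the proportion of the
condition's cells in a cluster with the proportion of unselected cells
in the same cluster, compared by a two-sided exact Wilcoxon signed-rank
test across mice (normal approximation beyond 25 mice). With n mice the
smallest attainable two-sided p is 2^(1−n) — 0.03125 at n = 6 — so
"significance" is only meaningful with enough animals; ties (all paired
differences zero) are reported as untestable with p = 1. The pairing
against unselected occupancy is this package's operationalisation of
"expected from the unselected population"; the source method statement
does not spell the statistic out.

## The GF-ICF transform

The core transform re-weights a normalised gene-by-cell matrix C so that
rarely detected genes carry signal comparable to abundant ones:

* gene frequency: G_f[x, c] = log2(1 + C[x, c]). The pseudocount is the
  minimal repair of the log at zero and preserves sparsity. Genes
  detected in fewer than 2 cells are dropped — co-clustering needs
  repeated observation.
* inverse cell frequency: ICF_x = log10(Σ_y W_y · N_y / (1 + E_{y,x})),
  where N_y is the cell count of sorted condition y, E_{y,x} the number
  of those cells detecting gene x, and W the expected population
  fractions of the five conditions (TSPAN8+ 0.07, TSPAN8− 0.93, GP2+
  0.02, GP2− 0.98, unselected 1.00). The weights are population
  fractions, not mixture proportions, and intentionally do not sum to
  one. A gene detected in 25% of a subset contributes an inverse
  frequency of 4 from that subset. Conditions absent from a given
  experiment are omitted. If the weighted sum falls below 1 (a gene
  detected in nearly every cell) the log goes negative; such values are
  clamped to 0 and flagged, because a negative weight would invert the
  transform's intent (`clamp_negative = FALSE` keeps them).
* GF_ICF = diag(ICF) · G_f.

## Gene embedding and module extraction

A rank-50 SVD of GF_ICF is computed via the Gram matrix of the smaller
side. Pairwise gene distances are cosine distances between gene rows of
the rank-50 representation U·diag(d). The alternative of using raw U
rows (each singular vector normalised to unit length) is available as
`component_weights = "none"`, but is not the default: it gives the
weakest retained component the same influence as the strongest, and in
data whose signal rank is below 50 the surplus components are pure noise
that dominates the distance — in our planted-truth experiments it made
well-separated modules unrecoverable while U·diag(d) recovered them.

The 2-D map is an exact t-SNE run on the precomputed distance matrix
(perplexity 50, 1000 iterations, early exaggeration 12 for 250
iterations, learning rate 200, seeded initialisation); the gradient loop
is compiled code, the perplexity calibration a bisection per gene.
Modules are extracted with HDBSCAN on the 2-D coordinates:
single-linkage over mutual-reachability distances, tree condensation at
`min_cluster_size = 20`, excess-of-mass cluster selection (root
excluded), membership probability = ratio of the gene's departure
density to the cluster's maximum density, unassigned genes labelled
noise with probability 0. The density estimate uses `min_samples = 5`
nearest neighbours: on a 2-D map this finer resolution keeps borderline
module members assigned, where the coarse canonical choice
(`min_samples = min_cluster_size`) strands a halo of genes as noise.
Every gene receives at most one module label.

## Robustness and the AMI

Module stability is scored by rerunning the entire
transform-and-cluster chain on random cell subsets (default 100 subsets
of 80% of cells, drawn without replacement, with the per-subset
detection counts N and E recomputed) and comparing all partition pairs
with adjusted mutual information. Noise is treated as an ordinary
cluster label, genes absent from a subset join it, and the AMI uses the
permutation-model expected MI with the arithmetic mean of entropies as
normaliser. The t-SNE seed is held fixed across subsets so the score
isolates sensitivity to the data, not to the map initialisation;
identical subsets therefore give AMI exactly 1. Whether the original
analysis subsampled cells or mice is not stated; cells are assumed.

## Module composition statistics

Enrichment questions about module contents (TRGs, chromosomes,
arbitrary tissue-specific or auto-antigen gene panels) share one Monte
Carlo engine: the null for a module of size s is the statistic of s
genes drawn uniformly without replacement from the clustered universe
(assigned + noise genes), repeated n_perm times (default 10,000).
Empirical p-values use the add-one rule (1 + #{null ≥ obs})/(n_perm +
1), so they are never zero; two-sided p doubles the smaller tail;
Benjamini–Hochberg corrects across modules (chromosome tests correct
across all module × chromosome cells, flagged at adjusted p < 0.01).
The single-category case is exactly hypergeometric, which the test
suite uses as a closed-form oracle. Pairwise genomic distances (gene
start to gene start, same chromosome only) are compared between the
full universe, AIRE-regulated genes and within-module pairs by
two-sample Kolmogorov–Smirnov tests.

## Cross-mouse co-expression reproducibility

For a TRG panel, f(Gx, Gy) is the fraction of one mouse's cells
detecting both genes (raw count ≥ 1 — detection semantics match the
transform). Pearson correlations of these frequency vectors are
computed for every mouse pair; mouse-vs-pooled correlations are
reported separately and are not folded into the headline mean, since
the pooled vector is not independent of the mice. Pairs never
co-detected in any mouse are dropped by default (all-zero vectors carry
no signal and deflate r); zero-variance vectors make a pair undefined
and excluded with a warning. The full pair set is quadratic in the
panel, so a seeded `max_pairs` subsample supports desk-scale runs.

## Spatial analysis

The medullary mask comes from the cytokeratin-like channel: Gaussian
blur (sigma ~4 px for 512×512 images, ~8 px for 1980×1980), Otsu
threshold (overridable), erosion, dilation, small-component removal.
Marker-positive cells are segmented the same way plus a watershed split
of touching features; centroids are intensity-weighted first moments.
G(r), the empirical CDF of nearest-neighbour distances, is computed
without analytic edge correction: all inference is envelope-based, with
reference patterns simulated inside the same mask, which cancels edge
and mask-shape effects for arbitrary mask geometry. Reference
processes: random = uniform over mask pixels (sub-pixel jittered);
even = sequential inhibition with radius 0.7/sqrt(n/area); clustered =
parent–offspring with 5 parents and offspring spread 5% of the mask
bounding-box diagonal. The envelope spans the
simulation extremes over ≥ 99 seeded runs — the classical global
envelope. Narrower pointwise quantile bands are exited somewhere on the
grid by most draws of the reference process itself (neighbouring G
values are correlated, but a 50-point grid still offers several
effectively independent chances), which would misclassify genuinely
random patterns. Classification: random if the observed G stays inside
the random envelope at ≥ 95% of grid points; otherwise the direction of
the first excursion decides (above = clustered, below = even) — the
first excursion is used because an inhibition pattern's G, after
staying below the band at small r, jumps steeply and can overshoot the
band's upper edge at moderate r. The classification grid starts at
`r_min` (default 4 × the marker blur sigma): nearest-neighbour
distances below the segmentation's feature-fusion scale are not
observable (touching cells become one label), and including them biases
a random pattern towards "even". For heavily fused images an explicit
`fuse_radius` can additionally apply the same fusion operator to the
reference simulations. The envelope test itself is this package's
operationalisation of "consistent with a random process"; the original
analysis shows exemplar curves without a formal band.

## The synthetic-data generator

The generator emulates the statistical shape of the study: five sort
conditions (TSPAN8±, GP2±, unselected; 600 cells each by default),
several mice with optional ±10% detection jitter, 2,000 genes of which
30% are TRGs (AIRE-dependent/-enhanced/-independent), 10 cell clusters,
and 5 planted modules of 40–80 genes. Each module is switched on in 1–2
clusters, with on-cluster sets pairwise distinct across modules — sparse
activity is what makes planted modules identifiable, and mirrors single
cells expressing only a few percent of TRGs. Genes of on-modules are
detected with probability 0.25, everything else 0.02; detected entries
draw 1 + NB(mu = mean_umi − 1, size = dispersion) UMIs (negative
binomial chosen as the standard overdispersed UMI model; the source
states no generative model). Sorted-positive cells are drawn into their
marker module's on-clusters with probability 0.5 — satellite-cluster
preference, not determinism. Ten clusters at 3,000 cells matches the
granularity of 15 reported clusters at ~6,900 cells. Chromosome
assignment is uniform over 20 synthetic 100 Mb chromosomes —
deliberately structureless, matching the null finding for genomic
clustering. Synthetic images place Gaussian spots inside an elliptical-
blob mask by the three reference processes; the 0.5-level set of the
smooth structural channel is the true mask.

What the generator does *not* emulate: ambient RNA, doublets, mouse-
level batch effects beyond detection-rate jitter, realistic optics
(PSFs, uneven illumination), or read-level noise. Passing tests
therefore demonstrate parameter recovery under clean planted structure,
not robustness to every artefact of real data.

## Problem sizes and numerical choices

The test suite runs the full recovery chain at 2,000 genes × 3,000
cells (five seeds), smaller robustness panels (a few hundred genes,
four subsets, shortened t-SNE runs) and spatial recovery on 256 × 256
px images with 35 spots of 2 px radius — at that spot size feature
fusion is rare at the planted clustering scale, so the centroids a
segmentation can see still carry the pattern; sizes are chosen so the
whole suite completes on a laptop-class single core. Subset runs in tests pass
`max_iter` below the 1000-iteration default as their own problem-size
choice; defaults are unchanged. Degenerate inputs are defined
behaviour: MAD = 0 removes nothing; zero-total cells are a named error;
duplicate points give G(0) > 0; zero-height dendrogram merges have
their density clamped finite; empty marker channels segment to zero
centroids.

## Known limitations

* Exact t-SNE and dense cosine distances are quadratic in genes;
  beyond ~30,000 genes memory becomes the binding constraint before
  time does.
* The Wilcoxon pairing for condition enrichment is an interpretation of
  an under-specified method statement (flagged above).
* The mean AMI of a robustness run depends on the subset fraction,
  which the source does not state (0.8 assumed).
* Batch correction is linear; a mutual-nearest-neighbour embedding can
  be plugged in but is not re-implemented.
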