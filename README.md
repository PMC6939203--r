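# pgemod

Is promiscuous gene expression (PGE) in single medullary thymic
epithelial cells (mTEC) stochastic, or organised into recurring
programmes? mTEC collectively express most protein-coding genes to
enforce central tolerance, yet each cell detectably expresses only a few
percent of tissue-restricted genes (TRGs) at a time. `pgemod` is an R
package for analysts of sorted single-cell mTEC data (TSPAN8±, GP2±,
unselected) who want to answer that question quantitatively: it
discovers gene co-expression modules, scores their stability and
cross-animal reproducibility, characterises their composition, and tests
whether marker-positive mTEC are spatially random in tissue sections.

## The methods at the core

* **Weighted GF-ICF transform.** On the normalised count matrix C,
  gene frequency `G_f = log2(1 + C)` and inverse cell frequency
  `ICF_x = log10( Σ_y W_y · N_y / (1 + E_{y,x}) )`, where `N_y` is the
  cell count of sort condition y, `E_{y,x}` the number of those cells
  detecting gene x, and `W` the expected population fractions
  (TSPAN8+ 0.07, TSPAN8− 0.93, GP2+ 0.02, GP2− 0.98, unselected 1.00).
  `GF_ICF = diag(ICF) · G_f` up-weights rarely detected genes — the
  TF-IDF idea transplanted to sparse UMI data.
* **Module discovery.** Rank-50 SVD of GF-ICF, cosine distances between
  gene rows of the reduced representation, exact t-SNE to 2-D, HDBSCAN
  density clustering (noise allowed, membership probabilities
  reported).
* **Stability.** The whole chain re-run on random cell subsets;
  partitions compared by adjusted mutual information (AMI, noise as a
  cluster, permutation-model expectation).
* **Composition.** Monte Carlo enrichment of TRGs, chromosomes and
  arbitrary gene sets per module (add-one empirical p, BH correction);
  same-chromosome pairwise distance ECDFs with KS comparisons.
* **Reproducibility.** Per-mouse pairwise co-detection frequencies
  f(Gx, Gy) and their cross-mouse Pearson correlations.
* **Spatial order.** Medulla mask + marker-cell segmentation
  (blur/threshold/morphology/watershed), nearest-neighbour G-function,
  and classification against mask-confined simulation envelopes of
  even, random and clustered point processes.

A synthetic-data generator plants known modules, cell clusters,
condition couplings and point patterns, so every stage is validated by
parameter recovery.

## Worked example

```r
library(pgemod)

sim <- generate_counts(sim_config(seed = 1))   # 2000 genes x 3000 cells
qc  <- filter_cells(sim$matrix)
mat <- normalise_counts(qc$matrix)

part <- gene_modules(mat, seed = 101)          # GF-ICF -> SVD -> t-SNE -> HDBSCAN
table(part$labels == 0)
#> FALSE  TRUE
#>  1990    10
part$n_modules
#> [1] 6

truth <- sim$truth$gene_module_labels[attr(part, "kept")]
adjusted_mutual_information(part$labels, truth)
#> [1] 0.9585228
```

The five planted modules are all recovered (one split into two
sub-modules, giving six labels); only 10 genes stay unassigned
(noise); the AMI against the planted truth — with noise treated as its
own cluster — is 0.96, near-perfect recovery of the planted programme.
On the spatial side:

```r
img <- generate_image(256, 256, kind = "clustered", n_points = 35,
                      spot_radius = 2, seed = 7)
res <- spatial_pattern_test(img$marker, img$structure, n_sim = 99,
                            seed = 1, spot_sigma = 1.5)
res$classification
#> [1] "clustered"
```

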