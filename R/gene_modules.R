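#' Default condition weights of the inverse cell frequency
#'
#' Expected contribution of each sorted condition to the total mTEC
#' population: TSPAN8+ 7%, TSPAN8- 93%, GP2+ 2%, GP2- 98%, unselected
#' 100%. The weights intentionally do not sum to one; they are raw
#' population fractions, not mixture proportions.
#'
#' @return Named numeric vector over [mtec_conditions()].
#' @export
default_icf_weights <- function() {
  c("TSPAN8+" = 0.07, "TSPAN8-" = 0.93, "GP2+" = 0.02,
    "GP2-" = 0.98, "unselected" = 1.00)
}

#' Per-condition detection counts feeding the inverse cell frequency
#'
#' Computes, for every gene x and condition y, the number of cells N_y
#' in the condition and the number E_{y,x} of those cells detecting the
#' gene (raw count >= 1). Conditions absent from the data (N_y = 0) are
#' dropped.
#'
#' @param x a [count_matrix()] (detection uses the stored counts > 0).
#' @param W named condition weights; default [default_icf_weights()].
#' @param cells optional cell index restricting the computation (used by
#'   the subsampling robustness machinery).
#' @return List of class `icf_weights`: `W`, `N` (named counts), `E`
#'   (genes x conditions matrix), `gene_id`.
#' @export
icf_weights <- function(x, W = default_icf_weights(), cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(W < 0)) stop("weights must be non-negative")
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  cond <- as.character(x$cell_meta$condition)[ci]
  det <- x$counts[, ci, drop = FALSE] > 0
  present <- intersect(names(W), unique(cond))
  if (!length(present)) stop("no cells in any weighted condition")
  E <- vapply(present, function(co)
    Matrix::rowSums(det[, cond == co, drop = FALSE]), numeric(nrow(det)))
  E <- matrix(E, nrow = nrow(det),
              dimnames = list(rownames(x$counts), present))
  N <- vapply(present, function(co) sum(cond == co), numeric(1))
  if (any(E < 0) || any(E > matrix(N, nrow(E), length(N), byrow = TRUE)))
    stop("inconsistent detection counts")
  structure(list(W = W[present], N = N, E = E,
                 gene_id = x$gene_meta$gene_id),
            class = "icf_weights")
}

#' Per-subset inverse frequency of detection
#'
#' The building block of the ICF: a gene detected in `n_expressing` of
#' `n_cells` cells of one subset has inverse cell frequency
#' `n_cells / n_expressing` (so 25% detection gives 4). The regularised
#' form `n_cells / (1 + n_expressing)` is what enters the weighted sum;
#' it converges to the plain ratio as the subset grows.
#'
#' @param n_cells subset size N_y.
#' @param n_expressing expressing-cell count E_{y,x}.
#' @param regularised use the `1 + E` denominator?
#' @return The inverse-frequency ratio.
#' @export
subset_inverse_frequency <- function(n_cells, n_expressing,
                                     regularised = FALSE) {
  stopifnot(n_cells >= 0, n_expressing >= 0, n_expressing <= n_cells)
  if (regularised) n_cells / (1 + n_expressing)
  else n_cells / n_expressing
}

#' Gene-frequency matrix G_f
#'
#' `G_f[x, c] = log2(1 + C[x, c])` on the normalised matrix (the
#' pseudocount makes the transform defined at zero and preserves
#' sparsity). Genes detected in fewer than `min_cells` cells are dropped:
#' co-clustering needs genes observed in multiple cells.
#'
#' @param x normalised [count_matrix()].
#' @param min_cells minimum detecting-cell count to retain a gene.
#' @return List: `gf` (sparse genes x cells), `kept` (row index into the
#'   input), `dropped` (gene ids removed).
#' @export
gene_frequency <- function(x, min_cells = 2) {
  stopifnot(inherits(x, "count_matrix"))
  det <- Matrix::rowSums(x$counts > 0)
  kept <- which(det >= min_cells)
  gf <- x$counts[kept, , drop = FALSE]
  gf@x <- log2(1 + gf@x)
  list(gf = gf, kept = kept,
       dropped = x$gene_meta$gene_id[det < min_cells])
}

#' Inverse cell frequency ICF_x
#'
#' `ICF_x = log10(sum_y W_y * N_y / (1 + E_{y,x}))`: the log of the
#' weighted sum, over conditions, of the regularised inverse detection
#' frequencies. Genes detected in nearly every cell can push the sum
#' below 1 and the log below 0; such entries are clamped to 0 (and
#' flagged) by default, because a negative weight would invert the
#' transform's up-weighting intent.
#'
#' @param weights an [icf_weights()] object.
#' @param clamp_negative clamp negative ICF values to zero?
#' @return Numeric vector (one per gene) with attribute `clamped`
#'   (logical vector marking affected genes).
#' @export
inverse_cell_frequency <- function(weights, clamp_negative = TRUE) {
  stopifnot(inherits(weights, "icf_weights"))
  contrib <- sweep(1 / (1 + weights$E), 2,
                   weights$W * weights$N, "*")
  icf <- log10(rowSums(contrib))
  clamped <- icf < 0
  if (clamp_negative) icf[clamped] <- 0
  attr(icf, "clamped") <- clamped
  names(icf) <- weights$gene_id
  icf
}

#' GF-ICF product matrix
#'
#' Scales row x of the gene-frequency matrix by `icf[x]`. The sparsity
#' pattern of `gf` is preserved.
#'
#' @param gf sparse gene-frequency matrix (rows named by gene id), e.g.
#'   `gene_frequency(x)$gf`.
#' @param icf named ICF vector covering exactly the genes of `gf`.
#' @return Sparse genes x cells matrix.
#' @export
gf_icf <- function(gf, icf) {
  ids <- rownames(gf)
  if (is.null(ids) || is.null(names(icf)))
    stop("gf rows and icf must be named by gene id")
  if (!all(ids %in% names(icf)))
    stop("icf is missing ", sum(!ids %in% names(icf)), " genes of gf")
  out <- Matrix::Diagonal(x = unname(icf[ids])) %*% gf
  dimnames(out) <- dimnames(gf)
  out
}

#' Embed genes by SVD and t-SNE of cosine distances
#'
#' Truncated SVD of the GF-ICF matrix (via the Gram matrix of the
#' smaller side), cosine distances between the gene rows of the rank-k
#' representation, then a 2-D t-SNE of the precomputed distance matrix.
#' All intermediates are retained.
#'
#' By default the gene representation is `U \%*\% diag(d)` — the gene
#' rows of the rank-k approximation of GF-ICF — so every retained
#' component contributes in proportion to its singular value. With
#' `component_weights = "none"` the raw left singular vectors are used
#' instead, which gives the weakest components the same say as the
#' strongest and lets pure-noise directions dominate the cosine.
#'
#' @param m sparse GF-ICF matrix (genes x cells).
#' @param n_components number of singular vectors (default 50).
#' @param perplexity,max_iter t-SNE settings.
#' @param seed integer seed for the t-SNE initialisation.
#' @param component_weights `"singular"` (rows of U d, default) or
#'   `"none"` (rows of U).
#' @return List of class `gene_embedding`: `singular_values`,
#'   `left_vectors` (genes x k), `cosine_distances`, `coords2d`, `seed`.
#' @export
embed_genes <- function(m, n_components = 50, perplexity = 50,
                        max_iter = 1000, seed = 1L,
                        component_weights = c("singular", "none")) {
  component_weights <- match.arg(component_weights)
  ng <- nrow(m); nc <- ncol(m)
  if (ng < n_components)
    stop("fewer genes (", ng, ") than components (", n_components, ")")
  k <- min(n_components, ng, nc)
  if (ng <= nc) {
    K <- as.matrix(Matrix::tcrossprod(m))
    e <- eigen(K, symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    U <- e$vectors[, seq_len(k), drop = FALSE]
  } else {
    K <- as.matrix(Matrix::crossprod(m))
    e <- eigen(K, symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    V <- e$vectors[, seq_len(k), drop = FALSE]
    U <- as.matrix(m %*% V)
    pos <- d > max(d) * 1e-12
    U[, pos] <- sweep(U[, pos, drop = FALSE], 2, d[pos], "/")
    U[, !pos] <- 0
  }
  R <- if (component_weights == "singular")
    sweep(U, 2, pmax(d, max(d) * 1e-12), "*") else U
  D <- cosine_distance(R)
  Z <- tsne_embed(D, dims = 2, perplexity = perplexity,
                  max_iter = max_iter, seed = seed)
  rownames(U) <- rownames(m)
  rownames(Z) <- rownames(m)
  structure(list(singular_values = d, left_vectors = U,
                 cosine_distances = D, coords2d = Z,
                 seed = as.integer(seed)),
            class = "gene_embedding")
}

# pairwise cosine distance between rows; zero rows are at distance 1
# from everything (orthogonal convention)
cosine_distance <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  z <- nrm == 0
  nrm[z] <- 1
  Un <- U / nrm
  D <- 1 - tcrossprod(Un)
  D[z, ] <- 1; D[, z] <- 1
  diag(D) <- 0
  pmin(pmax(D, 0), 2)
}

#' Density clustering of the 2-D gene map into modules
#'
#' Runs [hdbscan_cluster()] on the t-SNE coordinates; genes outside any
#' dense region are labelled noise (0) with membership probability 0.
#'
#' @param emb a `gene_embedding`.
#' @param min_cluster_size smallest admissible module (default 20).
#' @param min_samples neighbour count of the density estimate. The small
#'   default resolves density finely on a 2-D map, keeping borderline
#'   module members assigned; raise it for a more conservative
#'   partition.
#' @return List of class `gene_module_partition`: `labels` (0 = noise),
#'   `probabilities`, `n_modules`, `gene_id`.
#' @export
cluster_genes <- function(emb, min_cluster_size = 20, min_samples = 5) {
  stopifnot(inherits(emb, "gene_embedding"))
  fit <- hdbscan_cluster(emb$coords2d,
                         min_cluster_size = min_cluster_size,
                         min_samples = min_samples)
  structure(list(labels = fit$labels,
                 probabilities = fit$probabilities,
                 n_modules = fit$n_clusters,
                 gene_id = rownames(emb$coords2d)),
            class = "gene_module_partition")
}

#' Full gene-module discovery chain
#'
#' Convenience wrapper: gene frequency -> ICF -> GF-ICF -> SVD/t-SNE
#' embedding -> density modules, on a normalised count matrix.
#'
#' @param x normalised [count_matrix()].
#' @param W condition weights.
#' @param n_components,perplexity,max_iter,min_cluster_size,min_samples,seed
#'   forwarded to the stages.
#' @param cells optional cell subset (index) on which the whole chain —
#'   including the N/E detection counts — is recomputed.
#' @return A `gene_module_partition` with attributes `embedding` and
#'   `kept` (row index of clustered genes in `x`).
#' @export
gene_modules <- function(x, W = default_icf_weights(), n_components = 50,
                         perplexity = 50, max_iter = 1000,
                         min_cluster_size = 20, min_samples = 5,
                         seed = 1L, cells = NULL) {
  xs <- if (is.null(cells)) x else subset_cells(x, cells = cells)
  gfr <- gene_frequency(xs)
  w <- icf_weights(xs, W)
  icf <- inverse_cell_frequency(w)
  m <- gf_icf(gfr$gf, icf)
  emb <- embed_genes(m, n_components = n_components,
                     perplexity = perplexity, max_iter = max_iter,
                     seed = seed)
  part <- cluster_genes(emb, min_cluster_size = min_cluster_size,
                        min_samples = min_samples)
  attr(part, "embedding") <- emb
  attr(part, "kept") <- gfr$kept
  part
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement: `AMI = (MI - E[MI]) / (mean(H_a, H_b) -
#' E[MI])`, with the expected mutual information taken under the
#' permutation (hypergeometric) model and the arithmetic mean of
#' entropies as normaliser. Noise labels must be mapped to an ordinary
#' cluster label before the call (0 is treated as such a label here).
#'
#' @param a,b label vectors over the same universe (any atomic type).
#' @return A single number <= 1; 1 for identical partitions (up to
#'   relabelling).
#' @export
adjusted_mutual_information <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions cover different universes (", length(a), " vs ",
         length(b), ")")
  N <- length(a)
  ct <- table(a, b)
  ai <- rowSums(ct); bj <- colSums(ct)
  Ha <- entropy_counts(ai, N); Hb <- entropy_counts(bj, N)
  if (Ha == 0 && Hb == 0) return(1)
  mi <- 0
  nz <- which(ct > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    nij <- ct[nz[r, 1], nz[r, 2]]
    mi <- mi + (nij / N) *
      log(N * nij / (ai[nz[r, 1]] * bj[nz[r, 2]]))
  }
  emi <- expected_mi(ai, bj, N)
  denom <- (Ha + Hb) / 2 - emi
  if (abs(denom) < 1e-15) return(if (abs(mi - emi) < 1e-15) 1 else 0)
  unname((mi - emi) / denom)
}

entropy_counts <- function(cnt, N) {
  p <- cnt[cnt > 0] / N
  -sum(p * log(p))
}

# E[MI] under random permutation of labels with fixed marginals
expected_mi <- function(ai, bj, N) {
  emi <- 0
  lgN <- lgamma(N + 1)
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - N)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(N - ai[i] + 1) + lgamma(N - bj[j] + 1) -
        lgN - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) -
        lgamma(bj[j] - nij + 1) -
        lgamma(N - ai[i] - bj[j] + nij + 1)
      term <- (nij / N) * log(N * nij / (ai[i] * bj[j]))
      emi <- emi + sum(exp(lp) * term)
    }
  }
  emi
}

#' Module robustness by cell subsampling and pairwise AMI
#'
#' Reruns the entire transform-and-cluster chain on `n_subsets` random
#' subsets of cells (fraction `subset_fraction`, sampled without
#' replacement; detection counts N/E are recomputed per subset), maps
#' every partition back to the common gene universe (genes absent from a
#' subset join the noise cluster) and scores all pairwise adjusted
#' mutual informations.
#'
#' @param x normalised [count_matrix()].
#' @param W condition weights.
#' @param n_subsets number of random subsets (default 100).
#' @param subset_fraction cell fraction per subset, in (0, 1].
#' @param seed integer master seed (one sub-seed per subset).
#' @param ... forwarded to [gene_modules()].
#' @return List of class `robustness_result`: `n_subsets`,
#'   `subset_fraction`, `pairwise_ami`, `mean_ami`, `partitions`
#'   (matrix genes x subsets, 0 = noise/unclustered).
#' @export
module_robustness <- function(x, W = default_icf_weights(),
                              n_subsets = 100, subset_fraction = 0.8,
                              seed = 1L, ...) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1)
  nc <- ncol(x$counts)
  ns <- max(2L, round(subset_fraction * nc))
  parts <- matrix(0L, nrow(x$counts), n_subsets)
  for (s in seq_len(n_subsets)) {
    set.seed(sub_seed(seed, paste0("subset", s)))
    cells <- if (subset_fraction == 1) seq_len(nc)
             else sample.int(nc, ns)
    # the map seed is held fixed so the score isolates sensitivity to
    # the cell subsample (identical subsets give identical partitions)
    p <- gene_modules(x, W = W, cells = cells, seed = seed, ...)
    parts[attr(p, "kept"), s] <- p$labels
  }
  pairs <- utils::combn(n_subsets, 2)
  amis <- apply(pairs, 2, function(ij)
    adjusted_mutual_information(parts[, ij[1]], parts[, ij[2]]))
  structure(list(n_subsets = n_subsets,
                 subset_fraction = subset_fraction,
                 pairwise_ami = amis,
                 mean_ami = mean(amis),
                 partitions = parts),
            class = "robustness_result")
}
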