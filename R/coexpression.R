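#' Pairwise co-detection frequencies per mouse
#'
#' For every unordered pair of genes in `gene_set`, the fraction
#' f(Gx, Gy) of a mouse's cells in which both genes are detected (raw
#' count >= 1), plus the pooled fraction over all cells. An optional
#' cluster selection restricts the cells first (e.g. the AIRE+ mature
#' analogue of restricting to particular cell clusters).
#'
#' @param x a [count_matrix()] with `mouse_id` per cell.
#' @param gene_set character vector of gene ids (>= 2 after matching).
#' @param cell_filter optional logical/integer cell index applied before
#'   anything else (e.g. `cluster_labels %in% 3:6`).
#' @param max_pairs optional cap on the number of pairs, drawn by seeded
#'   uniform sampling of the pair list (desk-scale runs).
#' @param seed seed for the pair subsample.
#' @return List of class `coexpression_frequencies`: `pairs` (2-column
#'   matrix of gene ids), `per_mouse` (pairs x mice matrix), `pooled`,
#'   `n_cells` (per mouse), `cell_filter` description.
#' @export
coexpression_frequencies <- function(x, gene_set, cell_filter = NULL,
                                     max_pairs = NULL, seed = 1L) {
  stopifnot(inherits(x, "count_matrix"))
  xs <- if (is.null(cell_filter)) x else subset_cells(x, cells = cell_filter)
  gi <- match(intersect(gene_set, xs$gene_meta$gene_id),
              xs$gene_meta$gene_id)
  if (length(gi) < 2) stop("need at least 2 genes of gene_set in the matrix")
  mouse <- as.character(xs$cell_meta$mouse_id)
  mice <- sort(unique(mouse))
  n_by_mouse <- table(mouse)[mice]
  empty <- names(n_by_mouse)[n_by_mouse == 0]
  if (length(empty)) {
    warning("mice with zero cells excluded: ",
            paste(empty, collapse = ", "))
    mice <- setdiff(mice, empty)
  }
  det <- xs$counts[gi, , drop = FALSE] > 0
  ng <- length(gi)
  pair_idx <- which(upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
  if (!is.null(max_pairs) && nrow(pair_idx) > max_pairs) {
    set.seed(as.integer(seed))
    pair_idx <- pair_idx[sample.int(nrow(pair_idx), max_pairs), ,
                         drop = FALSE]
  }
  lin <- (pair_idx[, 2] - 1) * ng + pair_idx[, 1]   # column-major index
  co_freq <- function(cells) {
    dm <- det[, cells, drop = FALSE]
    co <- as.matrix(Matrix::tcrossprod(dm * 1)) / length(cells)
    co[lin]
  }
  per_mouse <- vapply(mice, function(m) co_freq(which(mouse == m)),
                      numeric(nrow(pair_idx)))
  pooled <- co_freq(seq_len(ncol(det)))
  ids <- xs$gene_meta$gene_id[gi]
  structure(list(pairs = cbind(gene_x = ids[pair_idx[, 1]],
                               gene_y = ids[pair_idx[, 2]]),
                 per_mouse = per_mouse,
                 pooled = pooled,
                 n_cells = as.integer(table(mouse)[mice]),
                 mice = mice,
                 cell_filter = if (is.null(cell_filter)) "all cells"
                               else "filtered"),
            class = "coexpression_frequencies")
}

#' Cross-mouse Pearson correlation of co-detection frequencies
#'
#' Pearson r of the paired frequency vectors for every unordered mouse
#' pair; mouse-vs-pooled comparisons are reported separately and are not
#' part of the headline mean. Pairs of genes never co-detected in any
#' mouse are dropped first by default (all-zero vectors carry no
#' signal); zero-variance vectors make a mouse pair undefined, which is
#' flagged and excluded from the mean with a warning.
#'
#' @param freqs a [coexpression_frequencies()] result.
#' @param drop_zero_pairs drop gene pairs with f = 0 in every mouse?
#' @return List of class `correlation_summary`: `pairwise_r` (named
#'   vector, `"m1|m2"`), `mean_r`, `pooled_r` (per-mouse r against the
#'   pooled vector), `mean_pooled_r`, `n_pairs_used`.
#' @export
cross_mouse_correlation <- function(freqs, drop_zero_pairs = TRUE) {
  stopifnot(inherits(freqs, "coexpression_frequencies"))
  M <- freqs$per_mouse
  if (ncol(M) < 2 && is.null(dim(M))) M <- matrix(M, ncol = 1)
  keep <- if (drop_zero_pairs) rowSums(M) > 0 else rep(TRUE, nrow(M))
  M <- M[keep, , drop = FALSE]
  pooled <- freqs$pooled[keep]
  mice <- freqs$mice
  if (length(mice) == 1) {
    return(structure(list(pairwise_r = stats::setNames(1, paste(
      mice, mice, sep = "|")), mean_r = 1,
      pooled_r = stats::cor(M[, 1], pooled), mean_pooled_r = NA_real_,
      n_pairs_used = nrow(M)), class = "correlation_summary"))
  }
  combs <- utils::combn(length(mice), 2)
  r <- apply(combs, 2, function(ij) {
    a <- M[, ij[1]]; b <- M[, ij[2]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  })
  names(r) <- apply(combs, 2, function(ij)
    paste(mice[ij[1]], mice[ij[2]], sep = "|"))
  if (anyNA(r))
    warning(sum(is.na(r)), " mouse pair(s) undefined ",
            "(zero variance) and excluded from the mean")
  pooled_r <- vapply(seq_along(mice), function(i)
    if (stats::sd(M[, i]) == 0 || stats::sd(pooled) == 0) NA_real_
    else stats::cor(M[, i], pooled), numeric(1))
  names(pooled_r) <- mice
  structure(list(pairwise_r = r,
                 mean_r = mean(r, na.rm = TRUE),
                 pooled_r = pooled_r,
                 mean_pooled_r = mean(pooled_r, na.rm = TRUE),
                 n_pairs_used = nrow(M)),
            class = "correlation_summary")
}
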