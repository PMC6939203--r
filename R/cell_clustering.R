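#' Shared-nearest-neighbour graph of cells
#'
#' Connects two cells when their k-nearest-neighbour sets (self excluded)
#' share at least one member; the edge weight is the Jaccard index of the
#' two sets. The graph is undirected, self-edge free and invariant (up to
#' relabelling) under permutation of cell order.
#'
#' @param embedding numeric matrix, cells x dimensions (e.g. from
#'   [correct_batches()]).
#' @param k neighbourhood size, `0 < k < n_cells`.
#' @return An [igraph::graph] with `weight` edge attribute in (0, 1].
#' @export
build_snn_graph <- function(embedding, k = 10) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k <= 0) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(A)            # |NN_i intersect NN_j|
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j & shared@x > 0
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * k - shared@x[keep])   # Jaccard
  g <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j, weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  if (!is.null(rownames(embedding)))
    igraph::V(g)$cell_id <- rownames(embedding)
  g
}

#' Louvain community detection on an SNN graph
#'
#' Two-phase modularity maximisation (local moves, then graph
#' aggregation, iterated to convergence) as implemented in igraph, with
#' the node visit order randomised by `seed`.
#'
#' @param graph an [igraph::graph] with a `weight` edge attribute.
#' @param seed integer seed controlling the (stochastic) visit order.
#' @param resolution modularity resolution (1 = standard modularity).
#' @return List of class `cell_partition`: `labels` (integer per cell),
#'   `modularity`, `seed`, `n_clusters`.
#' @export
louvain_cluster <- function(graph, seed = 1L, resolution = 1) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(graph,
                                weights = igraph::E(graph)$weight,
                                resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  structure(list(labels = labels,
                 modularity = max(cl$modularity),
                 seed = as.integer(seed),
                 n_clusters = length(unique(labels))),
            class = "cell_partition")
}

#' Recursively sub-cluster one cell cluster
#'
#' Re-runs SNN + Louvain on the cells of a single cluster, returning the
#' partition with that cluster split into sub-clusters (new labels are
#' appended after the existing maximum).
#'
#' @param partition a `cell_partition`.
#' @param embedding the full cell embedding used for the parent run.
#' @param cluster id of the cluster to split.
#' @param k,seed passed to [build_snn_graph()] / [louvain_cluster()].
#' @return An updated `cell_partition`.
#' @export
subcluster <- function(partition, embedding, cluster, k = 10, seed = 1L) {
  i <- which(partition$labels == cluster)
  if (length(i) <= k) stop("cluster too small to sub-cluster")
  sub <- louvain_cluster(build_snn_graph(embedding[i, , drop = FALSE], k),
                         seed = seed)
  labels <- partition$labels
  offset <- max(labels)
  labels[i] <- offset + sub$labels
  structure(list(labels = labels, modularity = partition$modularity,
                 seed = partition$seed,
                 n_clusters = length(unique(labels))),
            class = "cell_partition")
}

#' Test clusters for enrichment or depletion of sorted conditions
#'
#' For every cluster x sorted condition, the per-mouse proportion of that
#' condition's cells falling in the cluster is paired with the per-mouse
#' proportion of unselected cells in the same cluster (the expected
#' occupancy), and compared by a two-sided Wilcoxon signed-rank test
#' across mice (exact null for n <= 25 pairs). Direction is the sign of
#' the median paired difference.
#'
#' @param partition a `cell_partition` (or plain integer label vector).
#' @param cell_meta data.frame with `mouse_id` and `condition` columns,
#'   one row per cell, in the partition's cell order.
#' @return data.frame: cluster, condition, n_mice, direction
#'   (`"enriched"`/`"depleted"`/`"none"`), p_value (NA when untestable),
#'   untestable flag.
#' @export
condition_enrichment <- function(partition, cell_meta) {
  labels <- if (inherits(partition, "cell_partition"))
    partition$labels else as.integer(partition)
  stopifnot(length(labels) == nrow(cell_meta))
  cond <- as.character(cell_meta$condition)
  mouse <- as.character(cell_meta$mouse_id)
  clusters <- sort(unique(labels))
  tested <- setdiff(unique(cond), "unselected")
  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    for (co in tested) {
      # mice contributing both this condition and unselected cells
      mice <- intersect(unique(mouse[cond == co]),
                        unique(mouse[cond == "unselected"]))
      obs <- vapply(mice, function(m)
        mean(in_cl[cond == co & mouse == m]), numeric(1))
      expd <- vapply(mice, function(m)
        mean(in_cl[cond == "unselected" & mouse == m]), numeric(1))
      if (length(mice) < 2) {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, condition = co, n_mice = length(mice),
          direction = "none", p_value = NA_real_, untestable = TRUE)
        next
      }
      diffs <- obs - expd
      if (all(diffs == 0)) {
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl, condition = co, n_mice = length(mice),
          direction = "none", p_value = 1, untestable = TRUE)
        next
      }
      wt <- suppressWarnings(
        stats::wilcox.test(obs, expd, paired = TRUE,
                           exact = length(mice) <= 25))
      dir <- if (stats::median(diffs) > 0) "enriched"
             else if (stats::median(diffs) < 0) "depleted" else "none"
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, condition = co, n_mice = length(mice),
        direction = dir, p_value = wt$p.value, untestable = FALSE)
    }
  }
  do.call(rbind, out)
}
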