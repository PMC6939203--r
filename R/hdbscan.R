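#' Hierarchical density-based clustering (HDBSCAN)
#'
#' Density clustering of points via the mutual-reachability single-linkage
#' hierarchy: core distances are k-nearest-neighbour distances
#' (`k = min_samples`), the mutual reachability between two points is the
#' maximum of their core distances and their metric distance, the
#' single-linkage dendrogram over mutual reachabilities is condensed at
#' `min_cluster_size`, and flat clusters are extracted by the
#' excess-of-mass (stability) rule. Points not absorbed by any selected
#' cluster are labelled noise (0) with membership probability 0; member
#' probabilities are the ratio of the point's departure density
#' (lambda = 1 / dendrogram height) to the cluster's maximum density.
#'
#' @param x numeric matrix of coordinates (rows = points), or a
#'   `dist`/square distance matrix.
#' @param min_cluster_size smallest admissible cluster (>= 2).
#' @param min_samples neighbour count of the core distance; defaults to
#'   `min_cluster_size`.
#' @return List of class `hdbscan_fit`: `labels` (0 = noise),
#'   `probabilities`, `n_clusters`, `cluster_stability`.
#' @export
hdbscan_cluster <- function(x, min_cluster_size = 20,
                            min_samples = min_cluster_size) {
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  d <- if (inherits(x, "dist")) as.matrix(x)
       else if (is.matrix(x) && nrow(x) == ncol(x) &&
                isTRUE(all.equal(unname(x), unname(t(x))))) x
       else as.matrix(stats::dist(x))
  n <- nrow(d)
  if (n < 2 * min_cluster_size)
    return(structure(list(labels = integer(n),
                          probabilities = numeric(n),
                          n_clusters = 0L,
                          cluster_stability = numeric(0)),
                     class = "hdbscan_fit"))
  diag(d) <- Inf
  k <- min(min_samples, n - 1L)
  core <- apply(d, 1, function(r) sort.int(r, partial = k)[k])
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  condensed <- condense_tree(hc, n, min_cluster_size)
  extract_clusters(condensed, n)
}

# Walk the single-linkage dendrogram from the root, recording for every
# point the cluster it falls out of and the density (lambda) at which it
# does, and for every condensed cluster its parent, birth lambda and
# stability. Merge heights of zero are clamped so lambda stays finite.
condense_tree <- function(hc, n, mcs) {
  m <- nrow(hc$merge)
  h <- hc$height
  pos <- h[h > 0]
  eps <- if (length(pos)) min(pos) / 10 else 1e-12
  lam <- 1 / pmax(h, eps)

  sizes <- integer(m)                     # leaves under each merge node
  for (k in seq_len(m)) {
    ch <- hc$merge[k, ]
    sizes[k] <- sum(ifelse(ch < 0, 1L, sizes[pmax(ch, 1L)]))
  }

  # state per internal node: cluster id if active, or (cluster, lambda)
  # already-fallen marker propagated to the leaves
  state_cl <- integer(m); state_fallen <- logical(m)
  state_lam <- numeric(m)
  parent <- integer(0); birth <- numeric(0); stability <- numeric(0)
  new_cluster <- function(p, lb) {
    parent <<- c(parent, p); birth <<- c(birth, lb)
    stability <<- c(stability, 0)
    length(parent)
  }
  root <- new_cluster(0L, 0)
  state_cl[m] <- root
  fall_cluster <- integer(n); fall_lambda <- numeric(n)

  node_size <- function(ch) if (ch < 0) 1L else sizes[ch]
  drop_subtree <- function(ch, cl, lamv) {
    if (ch < 0) { fall_cluster[-ch] <<- cl; fall_lambda[-ch] <<- lamv }
    else { state_cl[ch] <<- cl; state_fallen[ch] <<- TRUE
           state_lam[ch] <<- lamv }
  }
  for (k in m:1) {
    ch <- hc$merge[k, ]
    if (state_fallen[k]) {
      drop_subtree(ch[1], state_cl[k], state_lam[k])
      drop_subtree(ch[2], state_cl[k], state_lam[k])
      next
    }
    cl <- state_cl[k]
    lamv <- lam[k]
    s1 <- node_size(ch[1]); s2 <- node_size(ch[2])
    if (s1 >= mcs && s2 >= mcs) {         # true split: two new clusters
      stability[cl] <- stability[cl] + sizes[k] * (lamv - birth[cl])
      a <- new_cluster(cl, lamv); b <- new_cluster(cl, lamv)
      state_cl[ch[1]] <- a                # both children internal
      state_cl[ch[2]] <- b                # (size >= mcs >= 2)
    } else if (s1 >= mcs || s2 >= mcs) {  # small side falls out
      big <- if (s1 >= mcs) ch[1] else ch[2]
      small <- if (s1 >= mcs) ch[2] else ch[1]
      stability[cl] <- stability[cl] +
        min(s1, s2) * (lamv - birth[cl])
      state_cl[big] <- cl
      drop_subtree(small, cl, lamv)
    } else {                              # cluster dissolves entirely
      stability[cl] <- stability[cl] + sizes[k] * (lamv - birth[cl])
      drop_subtree(ch[1], cl, lamv)
      drop_subtree(ch[2], cl, lamv)
    }
  }
  list(parent = parent, birth = birth, stability = stability,
       fall_cluster = fall_cluster, fall_lambda = fall_lambda,
       root = root)
}

# excess-of-mass cluster selection, root excluded, then point labels and
# membership probabilities
extract_clusters <- function(ct, n) {
  ncl <- length(ct$parent)
  children <- split(seq_len(ncl), factor(ct$parent, levels = 0:ncl))
  subtree_stab <- numeric(ncl)
  selected <- logical(ncl)
  for (c in ncl:1) {                      # children have larger index
    kids <- children[[as.character(c)]]
    kid_sum <- if (length(kids)) sum(subtree_stab[kids]) else 0
    if (c == ct$root) { subtree_stab[c] <- kid_sum; next }
    if (length(kids) == 0 || ct$stability[c] >= kid_sum) {
      selected[c] <- TRUE
      subtree_stab[c] <- ct$stability[c]
    } else subtree_stab[c] <- kid_sum
  }
  # final clusters: selected with no selected strict ancestor
  has_sel_anc <- function(c) {
    p <- ct$parent[c]
    while (p > 0) { if (selected[p]) return(TRUE); p <- ct$parent[p] }
    FALSE
  }
  sel_idx <- which(selected)
  final <- sel_idx[!vapply(sel_idx, has_sel_anc, logical(1))]
  # map every condensed cluster to its owning final cluster (if any)
  owner <- integer(ncl)
  for (c in seq_len(ncl)) {
    p <- c
    while (p > 0) { if (p %in% final) { owner[c] <- p; break }
                    p <- ct$parent[p] }
  }
  lab_of <- owner[ct$fall_cluster]
  labels <- match(lab_of, final, nomatch = 0L)
  labels[is.na(labels)] <- 0L
  probs <- numeric(n)
  for (fi in seq_along(final)) {
    mem <- labels == fi
    if (!any(mem)) next
    lmax <- max(ct$fall_lambda[mem])
    probs[mem] <- if (lmax > 0) ct$fall_lambda[mem] / lmax else 1
  }
  structure(list(labels = labels,
                 probabilities = pmin(probs, 1),
                 n_clusters = length(final),
                 cluster_stability = ct$stability[final]),
            class = "hdbscan_fit")
}
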