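#' Filter low-quality cells by MAD rules
#'
#' Removes cells whose total counts or detected-feature counts fall more
#' than `mad_reads`/`mad_features` median absolute deviations below the
#' batch median, or whose mitochondrial fraction lies more than
#' `mad_mito` MADs above it. Thresholds are recomputed independently per
#' batch by default (set `per_batch = FALSE` to pool). The MAD uses the
#' usual 1.4826 consistency constant (configurable).
#'
#' @param x raw [count_matrix()]; `cell_meta$mito_fraction` must exist
#'   (zeros are fine for synthetic data).
#' @param mad_reads,mad_features,mad_mito MAD multipliers of the three
#'   rules.
#' @param per_batch compute thresholds within each batch?
#' @param mad_constant consistency constant passed to [stats::mad()].
#' @return List with `matrix` (filtered `count_matrix`) and `report`
#'   (class `qc_report`: counts, per-batch thresholds, per-cell flags
#'   with failure reasons).
#' @export
filter_cells <- function(x, mad_reads = 1, mad_features = 1, mad_mito = 3,
                         per_batch = TRUE, mad_constant = 1.4826) {
  stopifnot(inherits(x, "count_matrix"))
  mito <- x$cell_meta$mito_fraction
  if (is.null(mito)) stop("cell_meta$mito_fraction is required")
  totals <- Matrix::colSums(x$counts)
  feats <- Matrix::colSums(x$counts > 0)
  batch <- if (per_batch && !is.null(x$cell_meta$batch))
    as.character(x$cell_meta$batch) else rep("all", ncol(x$counts))

  keep <- rep(TRUE, ncol(x$counts))
  reason <- rep("", ncol(x$counts))
  thr <- list()
  for (b in unique(batch)) {
    i <- which(batch == b)
    if (length(i) < 10) {
      warning("batch ", b, " has ", length(i),
              " cells (< 10); passed through unfiltered")
      thr[[b]] <- c(reads_min = NA, features_min = NA, mito_max = NA)
      next
    }
    t_reads <- stats::median(totals[i]) -
      mad_reads * stats::mad(totals[i], constant = mad_constant)
    t_feats <- stats::median(feats[i]) -
      mad_features * stats::mad(feats[i], constant = mad_constant)
    t_mito <- stats::median(mito[i]) +
      mad_mito * stats::mad(mito[i], constant = mad_constant)
    thr[[b]] <- c(reads_min = t_reads, features_min = t_feats,
                  mito_max = t_mito)
    bad_r <- totals[i] < t_reads
    bad_f <- feats[i] < t_feats
    bad_m <- mito[i] > t_mito
    keep[i] <- !(bad_r | bad_f | bad_m)
    reason[i] <- paste0(ifelse(bad_r, "low_reads;", ""),
                        ifelse(bad_f, "low_features;", ""),
                        ifelse(bad_m, "high_mito;", ""))
  }
  report <- structure(list(n_cells_in = ncol(x$counts),
                           n_cells_kept = sum(keep),
                           thresholds = thr,
                           keep = keep,
                           reason = reason),
                      class = "qc_report")
  list(matrix = subset_cells(x, cells = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: kept %d of %d cells\n",
              x$n_cells_kept, x$n_cells_in))
  for (b in names(x$thresholds))
    cat(sprintf("  %s: reads >= %.1f, features >= %.1f, mito <= %.4f\n",
                b, x$thresholds[[b]][1], x$thresholds[[b]][2],
                x$thresholds[[b]][3]))
  invisible(x)
}

#' Library-size normalisation to the median cell total
#'
#' Scales every cell so its total equals the median pre-normalisation
#' total (size factor = cell total / median total). Within-cell relative
#' proportions are conserved exactly; metadata are carried through.
#'
#' @param x filtered [count_matrix()] with every cell total > 0.
#' @return A normalised `count_matrix`.
#' @export
normalise_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- Matrix::colSums(x$counts)
  if (any(totals == 0))
    stop("zero-total cell(s): ",
         paste(utils::head(x$cell_meta$cell_id[totals == 0], 5),
               collapse = ", "))
  sf <- totals / stats::median(totals)
  norm <- x$counts %*% Matrix::Diagonal(x = 1 / sf)
  dimnames(norm) <- dimnames(x$counts)
  count_matrix(norm, x$gene_meta, x$cell_meta, normalised = TRUE)
}

#' Batch-corrected low-dimensional cell embedding
#'
#' The downstream graph clustering consumes an embedding, not a corrected
#' expression matrix. The built-in default computes a PCA of
#' log2(1 + normalised counts) and then centres each batch at the origin
#' in PC space — a deliberately simple linear correction. An externally
#' computed corrected embedding (e.g. mutual-nearest-neighbour output)
#' can be supplied instead and is passed through after a dimension check.
#'
#' @param x normalised [count_matrix()].
#' @param method `"pca_centre"` (default) or `"pca"` (no centring).
#' @param n_pcs number of principal components.
#' @param external optional cells x d matrix replacing the built-in
#'   embedding; must have one row per cell.
#' @return Numeric matrix, cells x `n_pcs` (or `ncol(external)`).
#' @export
correct_batches <- function(x, method = c("pca_centre", "pca"),
                            n_pcs = 50, external = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.null(external)) {
    if (nrow(external) != ncol(x$counts))
      stop("external embedding has ", nrow(external),
           " rows but matrix has ", ncol(x$counts), " cells")
    return(as.matrix(external))
  }
  method <- match.arg(method)
  Y <- Matrix::t(x$counts)
  Y@x <- log2(1 + Y@x)
  n_pcs <- min(n_pcs, ncol(Y) - 1L, nrow(Y) - 1L)
  emb <- truncated_pcs(Y, n_pcs)
  if (method == "pca_centre" && !is.null(x$cell_meta$batch)) {
    for (b in unique(x$cell_meta$batch)) {
      i <- x$cell_meta$batch == b
      emb[i, ] <- sweep(emb[i, , drop = FALSE], 2,
                        colMeans(emb[i, , drop = FALSE]))
    }
  }
  rownames(emb) <- x$cell_meta$cell_id
  emb
}

# top principal component scores of sparse rows-as-observations matrix,
# via an eigendecomposition of the smaller Gram matrix
truncated_pcs <- function(Y, k) {
  n <- nrow(Y); p <- ncol(Y)
  mu <- Matrix::colMeans(Y)
  if (p <= n) {
    G <- as.matrix(Matrix::crossprod(Y)) / n - tcrossprod(mu)   # p x p cov
    e <- eigen(G, symmetric = TRUE)
    V <- e$vectors[, seq_len(k), drop = FALSE]
    as.matrix(Y %*% V) - matrix(drop(crossprod(mu, V)), n, k, byrow = TRUE)
  } else {
    Xc <- as.matrix(Y) - matrix(mu, n, p, byrow = TRUE)
    K <- tcrossprod(Xc)                                          # n x n
    e <- eigen(K, symmetric = TRUE)
    d <- sqrt(pmax(e$values[seq_len(k)], 0))
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(d, k)
  }
}
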