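#' Sparse gene-by-cell count matrix with linked metadata
#'
#' The central container of the package: a sparse non-negative matrix of
#' UMI counts (genes in rows, cells in columns) together with per-gene and
#' per-cell annotation. Raw and normalised matrices share this class; the
#' `normalised` flag records which one you hold.
#'
#' @param counts sparse (or dense) non-negative numeric matrix, genes x cells.
#' @param gene_meta data.frame with one row per gene; must contain
#'   `gene_id`; typically also `chromosome`, `position_bp` and `category`
#'   (one of `"AIRE-dependent"`, `"AIRE-enhanced"`, `"AIRE-independent TRG"`,
#'   `"housekeeping"`, `"other"`, `"unclassified"`).
#' @param cell_meta data.frame with one row per cell; must contain
#'   `cell_id`; typically also `mouse_id`, `condition` (one of
#'   `"TSPAN8+"`, `"TSPAN8-"`, `"GP2+"`, `"GP2-"`, `"unselected"`),
#'   `batch` and `mito_fraction`.
#' @param normalised logical; has library-size normalisation been applied?
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_meta, cell_meta, normalised = FALSE) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.data.frame(gene_meta) || is.null(gene_meta$gene_id))
    stop("gene_meta must be a data.frame with a gene_id column")
  if (!is.data.frame(cell_meta) || is.null(cell_meta$cell_id))
    stop("cell_meta must be a data.frame with a cell_id column")
  if (nrow(gene_meta) != nrow(counts))
    stop("gene_meta has ", nrow(gene_meta), " rows but counts has ",
         nrow(counts), " genes")
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta has ", nrow(cell_meta), " rows but counts has ",
         ncol(counts), " cells")
  bad <- setdiff(unique(as.character(cell_meta$condition)),
                 c(mtec_conditions(), NA_character_))
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  rownames(counts) <- as.character(gene_meta$gene_id)
  colnames(counts) <- as.character(cell_meta$cell_id)
  structure(list(counts = counts,
                 gene_meta = as.data.frame(gene_meta),
                 cell_meta = as.data.frame(cell_meta),
                 normalised = isTRUE(normalised)),
            class = "count_matrix")
}

#' The five sorted mTEC conditions
#'
#' @return Character vector of the condition labels used throughout.
#' @export
mtec_conditions <- function() {
  c("TSPAN8+", "TSPAN8-", "GP2+", "GP2-", "unselected")
}

#' Gene categories counted as tissue-restricted genes (TRGs)
#'
#' @return Character vector of the categories whose union defines TRGs.
#' @export
trg_categories <- function() {
  c("AIRE-dependent", "AIRE-enhanced", "AIRE-independent TRG")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalised) "normalised" else "raw"))
  cat(sprintf("  nonzero entries: %d (%.1f%% dense)\n",
              length(x$counts@x),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (!is.null(x$cell_meta$condition))
    cat("  conditions:",
        paste(names(table(x$cell_meta$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or cell index
#'
#' @param x a `count_matrix`.
#' @param genes,cells integer, logical or character index; `NULL` keeps all.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  if (is.character(gi)) gi <- match(gi, x$gene_meta$gene_id)
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  if (is.character(ci)) ci <- match(ci, x$cell_meta$cell_id)
  count_matrix(x$counts[gi, ci, drop = FALSE],
               x$gene_meta[gi, , drop = FALSE],
               x$cell_meta[ci, , drop = FALSE],
               normalised = x$normalised)
}

#' Write a count matrix as Matrix Market plus TSV metadata
#'
#' Writes `matrix.mtx` (sparse counts), `genes.tsv` and `cells.tsv` into
#' `dir`, the on-disk layout consumed by [read_counts_dir()].
#'
#' @param x a `count_matrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_counts_dir <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(x$gene_meta, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_meta, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix from a Matrix Market directory
#'
#' Accepts either the layout written by [write_counts_dir()]
#' (`matrix.mtx` + `genes.tsv` + `cells.tsv`) or a 10x-style directory
#' (`matrix.mtx` + `features.tsv`/`genes.tsv` + `barcodes.tsv`, in which
#' case cell metadata holds only ids).
#'
#' @param dir directory path.
#' @param normalised logical flag stored on the returned object.
#' @return A `count_matrix`.
#' @export
read_counts_dir <- function(dir, normalised = FALSE) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  counts <- Matrix::readMM(mtx)
  gf <- Filter(file.exists,
               file.path(dir, c("genes.tsv", "features.tsv")))[1]
  if (is.na(gf)) stop("no genes.tsv/features.tsv under ", dir)
  genes <- utils::read.delim(gf, stringsAsFactors = FALSE)
  if (is.null(genes$gene_id)) {          # headerless 10x style
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)
    names(genes)[1] <- "gene_id"
  }
  cf <- file.path(dir, "cells.tsv")
  if (file.exists(cf)) {
    cells <- utils::read.delim(cf, stringsAsFactors = FALSE)
  } else {
    bc <- file.path(dir, "barcodes.tsv")
    if (!file.exists(bc)) stop("no cells.tsv/barcodes.tsv under ", dir)
    cells <- data.frame(cell_id = readLines(bc),
                        stringsAsFactors = FALSE)
  }
  count_matrix(counts, genes, cells, normalised = normalised)
}
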