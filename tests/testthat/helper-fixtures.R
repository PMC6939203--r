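# in-code fixtures shared across the suite

# a small dense-count matrix with explicit values and minimal metadata
toy_count_matrix <- function(counts, conditions = NULL, mice = NULL,
                             mito = NULL, batch = NULL,
                             normalised = FALSE) {
  ng <- nrow(counts); nc <- ncol(counts)
  count_matrix(
    counts,
    gene_meta = data.frame(gene_id = sprintf("g%03d", seq_len(ng)),
                           chromosome = "chr1",
                           position_bp = seq_len(ng) * 1000,
                           category = "other"),
    cell_meta = data.frame(cell_id = sprintf("c%03d", seq_len(nc)),
                           mouse_id = mice %||% rep("mouse01", nc),
                           condition = conditions %||%
                             rep("unselected", nc),
                           batch = batch %||% rep("b1", nc),
                           mito_fraction = mito %||% rep(0.05, nc)),
    normalised = normalised)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulation config that keeps test runtimes short
small_sim_config <- function(...) {
  defaults <- list(n_genes = 400,
                   n_cells_per_condition = c("TSPAN8+" = 120,
                                             "TSPAN8-" = 120,
                                             "GP2+" = 120, "GP2-" = 120,
                                             "unselected" = 120),
                   n_mice = 4, n_cell_clusters = 6, n_modules = 3,
                   module_size_range = c(25, 40), seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# naive loop implementations of the transform, used as oracles
naive_gene_frequency <- function(C) {
  out <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C)))
    for (j in seq_len(ncol(C)))
      out[i, j] <- log2(1 + C[i, j])
  out
}

naive_icf <- function(W, N, E) {
  icf <- numeric(nrow(E))
  for (x in seq_len(nrow(E))) {
    s <- 0
    for (y in seq_len(ncol(E)))
      s <- s + W[y] * N[y] / (1 + E[x, y])
    icf[x] <- log10(s)
  }
  icf
}

naive_gf_icf <- function(gf, icf) {
  out <- matrix(0, nrow(gf), ncol(gf))
  for (i in seq_len(nrow(gf)))
    for (j in seq_len(ncol(gf)))
      out[i, j] <- gf[i, j] * icf[i]
  out
}
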