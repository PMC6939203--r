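#' Configuration for the synthetic mTEC count generator
#'
#' Bundles every knob of the generator with validated defaults. The
#' defaults describe the study conditions emulated throughout the test
#' suite: five sort conditions, a handful of mice, sparse detection
#' (cells express a few percent of genes at baseline) and a small number
#' of planted co-expression modules switched on per cell cluster.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_condition named integer vector, cells per condition;
#'   names must be a subset of [mtec_conditions()].
#' @param n_mice number of mice the cells are split across.
#' @param n_cell_clusters number of planted cell subpopulations.
#' @param n_modules number of planted gene co-expression modules.
#' @param module_size_range length-2 integer range of module sizes (genes).
#' @param frac_trg fraction of genes labelled tissue-restricted (TRG).
#' @param baseline_detect_prob per-gene detection probability when the
#'   gene's module is off (or the gene is in no module).
#' @param active_detect_prob detection probability when the module is on;
#'   must exceed `baseline_detect_prob`.
#' @param mean_umi_per_gene mean UMI count of a detected entry (>= 1).
#' @param dispersion negative-binomial size parameter of detected counts.
#' @param n_chromosomes number of synthetic chromosomes (uniform gene
#'   placement on 100 Mb chromosomes; deliberately structureless).
#' @param on_clusters_range length-2 integer range: each module is
#'   switched on in this many cell clusters (drawn uniformly, clusters
#'   sampled without replacement). Small values keep module expression
#'   sparse, the way distinct mTEC subpopulations each run their own
#'   small programme.
#' @param condition_boost probability that a sorted-positive cell is
#'   drawn from its marker module's on-clusters instead of uniformly
#'   (see Details).
#' @param depth_multiplier named per-condition library-depth multiplier
#'   (defaults to 1 for every condition).
#' @param seed integer seed; the single source of randomness.
#'
#' @details Each sorted-positive condition (TSPAN8+, GP2+) designates one
#' module as its marker module; cells of that condition are assigned to
#' one of the marker module's on-clusters with probability
#' `condition_boost` (uniformly across clusters otherwise), mirroring
#' sorted subsets preferring particular satellite clusters.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_condition = c("TSPAN8+" = 600,
                                                 "TSPAN8-" = 600,
                                                 "GP2+" = 600,
                                                 "GP2-" = 600,
                                                 "unselected" = 600),
                       n_mice = 4,
                       n_cell_clusters = 10,
                       n_modules = 5,
                       module_size_range = c(40, 80),
                       frac_trg = 0.3,
                       baseline_detect_prob = 0.02,
                       active_detect_prob = 0.25,
                       mean_umi_per_gene = 2,
                       dispersion = 1,
                       n_chromosomes = 20,
                       on_clusters_range = c(1, 2),
                       condition_boost = 0.5,
                       depth_multiplier = NULL,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_condition = n_cells_per_condition,
              n_mice = as.integer(n_mice),
              n_cell_clusters = as.integer(n_cell_clusters),
              n_modules = as.integer(n_modules),
              module_size_range = as.integer(module_size_range),
              frac_trg = frac_trg,
              baseline_detect_prob = baseline_detect_prob,
              active_detect_prob = active_detect_prob,
              mean_umi_per_gene = mean_umi_per_gene,
              dispersion = dispersion,
              n_chromosomes = as.integer(n_chromosomes),
              on_clusters_range = as.integer(on_clusters_range),
              condition_boost = condition_boost,
              depth_multiplier = depth_multiplier,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1, n_mice >= 1, n_cell_clusters >= 1,
              n_modules >= 0, all(n_cells_per_condition >= 1),
              length(module_size_range) == 2,
              module_size_range[1] >= 1,
              module_size_range[1] <= module_size_range[2],
              frac_trg >= 0, frac_trg <= 1,
              baseline_detect_prob >= 0, baseline_detect_prob <= 1,
              active_detect_prob >= 0, active_detect_prob <= 1,
              mean_umi_per_gene > 0, dispersion > 0,
              n_chromosomes >= 1,
              length(on_clusters_range) == 2,
              on_clusters_range[1] >= 1,
              on_clusters_range[2] >= on_clusters_range[1])
    if (active_detect_prob <= baseline_detect_prob)
      stop("active_detect_prob must exceed baseline_detect_prob")
    if (!all(names(n_cells_per_condition) %in% mtec_conditions()))
      stop("n_cells_per_condition names must be mTEC conditions")
  })
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-stream seed for a named stage, below 2^31
sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + sum(utf8ToInt(stage))) %% 2147483587 + 1
}

#' Generate a synthetic count matrix with planted module structure
#'
#' Counts are drawn hierarchically: every cell belongs to a cluster; every
#' cluster switches a subset of gene modules on; genes of on-modules are
#' detected with `active_detect_prob`, everything else with
#' `baseline_detect_prob`; detected entries draw `1 + NB(mu, size)` UMIs.
#' Sorted-positive conditions force their marker module on (probability
#' `condition_boost`), coupling conditions to expression. The same seed
#' always yields bit-identical output.
#'
#' @param config a [sim_config()].
#' @param mouse_jitter per-mouse multiplicative detection-rate jitter
#'   half-width (0 disables; used by [generate_mouse_panel()]).
#' @param permute_modules_per_mouse if `TRUE`, each mouse receives an
#'   independently permuted gene-to-module assignment — a negative
#'   control destroying cross-mouse co-expression while keeping marginal
#'   statistics.
#' @return A list with elements `matrix` (a [count_matrix()]) and `truth`
#'   (planted labels: `gene_module_labels` with 0 = noise,
#'   `cell_cluster_labels`, `condition_labels`, `mouse_ids`,
#'   `cluster_module_on` activity matrix).
#' @export
generate_counts <- function(config = sim_config(), mouse_jitter = 0,
                            permute_modules_per_mouse = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nm <- config$n_modules

  # --- gene-level structure -------------------------------------------
  msr <- config$module_size_range
  sizes <- if (nm > 0)
    msr[1] + sample.int(msr[2] - msr[1] + 1L, nm, replace = TRUE) - 1L
  else integer(0)
  if (sum(sizes) > ng)
    stop("planted modules need ", sum(sizes), " genes but only ",
         ng, " available (deficit ", sum(sizes) - ng, ")")
  gene_module <- integer(ng)                       # 0 = noise
  idx <- sample.int(ng)                            # scatter module genes
  at <- 1L
  for (m in seq_len(nm)) {
    gene_module[idx[at:(at + sizes[m] - 1L)]] <- m
    at <- at + sizes[m]
  }
  chrom <- sample.int(config$n_chromosomes, ng, replace = TRUE)
  pos <- round(stats::runif(ng, 1, 1e8))
  n_trg <- round(config$frac_trg * ng)
  cat_lab <- rep("other", ng)
  trg_idx <- sample.int(ng, n_trg)
  cat_lab[trg_idx] <- sample(trg_categories(), n_trg, replace = TRUE,
                             prob = c(0.5, 0.2, 0.3))
  hk <- sample(which(cat_lab == "other"),
               min(round(0.1 * ng), sum(cat_lab == "other")))
  cat_lab[hk] <- "housekeeping"
  gene_meta <- data.frame(gene_id = sprintf("G%05d", seq_len(ng)),
                          chromosome = paste0("chr", chrom),
                          position_bp = pos,
                          category = cat_lab,
                          stringsAsFactors = FALSE)

  # cluster x module activity: each module runs in only a few clusters,
  # keeping module expression sparse across cells (every module keeps at
  # least one off cluster so the planted contrast always exists)
  on <- matrix(FALSE, config$n_cell_clusters, nm)
  ocr <- pmin(config$on_clusters_range, config$n_cell_clusters)
  seen <- character(0)
  for (m in seq_len(nm)) {
    for (try in 1:100) {                 # distinct on-sets keep planted
      n_on <- if (ocr[1] == ocr[2]) ocr[1]      # modules identifiable
              else sample(ocr[1]:ocr[2], 1)
      n_on <- min(n_on, max(config$n_cell_clusters - 1L, 1L))
      set <- sort(sample.int(config$n_cell_clusters, n_on))
      key <- paste(set, collapse = ",")
      if (!key %in% seen || try == 100L) break
    }
    if (key %in% seen)
      warning("module ", m, " shares its on-cluster set with another ",
              "module; planted contexts overlap")
    seen <- c(seen, key)
    on[set, m] <- TRUE
  }

  # --- cell-level structure -------------------------------------------
  conds <- rep(names(config$n_cells_per_condition),
               times = config$n_cells_per_condition)
  nc <- length(conds)
  cluster <- sample.int(config$n_cell_clusters, nc, replace = TRUE)
  # sorted-positive cells preferentially come from their marker
  # module's on-clusters (satellite-cluster enrichment)
  marker <- c("TSPAN8+" = if (nm >= 1) 1L else 0L,
              "GP2+" = if (nm >= 2) 2L else 0L)
  for (co in names(marker)) {
    m <- marker[[co]]
    if (m == 0) next
    home <- which(on[, m])
    if (!length(home)) next
    ci <- which(conds == co & stats::runif(nc) < config$condition_boost)
    if (length(ci))
      cluster[ci] <- home[1L + (seq_along(ci) %% length(home))]
  }
  mouse <- if (config$n_mice > nc)
    stop("n_mice (", config$n_mice, ") exceeds total cells (", nc, ")")
  else sprintf("mouse%02d", 1L + (sample.int(nc) %% config$n_mice))
  batch <- mouse                                   # one batch per mouse

  jit <- if (mouse_jitter > 0)
    stats::runif(config$n_mice, 1 - mouse_jitter, 1 + mouse_jitter)
  else rep(1, config$n_mice)
  names(jit) <- sprintf("mouse%02d", seq_len(config$n_mice))

  perm <- NULL
  if (permute_modules_per_mouse) {
    perm <- lapply(seq_len(config$n_mice), function(i) sample.int(ng))
    names(perm) <- names(jit)
  }

  depth <- rep(1, nc)
  if (!is.null(config$depth_multiplier))
    depth <- unname(config$depth_multiplier[conds])

  # --- draw detections and counts, grouped by identical probability row
  module_of_gene <- gene_module
  p_active <- config$active_detect_prob
  p_base <- config$baseline_detect_prob
  triplets_i <- vector("list", nc)
  triplets_x <- vector("list", nc)
  for (c in seq_len(nc)) {
    gm <- if (is.null(perm)) module_of_gene
          else module_of_gene[perm[[mouse[c]]]]
    mods_on <- on[cluster[c], ]
    active <- gm > 0 & mods_on[pmax(gm, 1L)]
    p <- ifelse(active, p_active, p_base) *
      jit[[mouse[c]]] * depth[c]
    p <- pmin(p, 1)
    det <- which(stats::runif(ng) < p)
    if (length(det)) {
      x <- 1 + stats::rnbinom(length(det),
                              mu = max(config$mean_umi_per_gene - 1, 0.01),
                              size = config$dispersion)
      triplets_i[[c]] <- det
      triplets_x[[c]] <- x
    }
  }
  nnz <- lengths(triplets_i)
  counts <- Matrix::sparseMatrix(
    i = unlist(triplets_i, use.names = FALSE),
    j = rep.int(seq_len(nc), nnz),
    x = as.numeric(unlist(triplets_x, use.names = FALSE)),
    dims = c(ng, nc))

  mito <- stats::rbeta(nc, 2, 38)                  # ~5% mitochondrial reads
  cell_meta <- data.frame(cell_id = sprintf("C%05d", seq_len(nc)),
                          mouse_id = mouse,
                          condition = conds,
                          batch = batch,
                          mito_fraction = mito,
                          stringsAsFactors = FALSE)
  cm <- count_matrix(counts, gene_meta, cell_meta, normalised = FALSE)
  truth <- list(gene_module_labels = gene_module,
                cell_cluster_labels = cluster,
                condition_labels = conds,
                mouse_ids = mouse,
                cluster_module_on = on,
                marker_modules = marker,
                module_permutation = perm)
  list(matrix = cm, truth = truth)
}

#' Generate a multi-mouse panel sharing (or not sharing) module structure
#'
#' Thin wrapper around [generate_counts()] that guarantees at least two
#' mice, applies per-mouse multiplicative detection jitter (default
#' +/-10%) and optionally destroys cross-mouse structure by permuting the
#' gene-to-module map independently per mouse (negative control).
#'
#' @inheritParams generate_counts
#' @return As [generate_counts()].
#' @export
generate_mouse_panel <- function(config = sim_config(), mouse_jitter = 0.1,
                                 permute_modules_per_mouse = FALSE) {
  if (config$n_mice > sum(config$n_cells_per_condition))
    stop("n_mice exceeds total cells")
  generate_counts(config, mouse_jitter = mouse_jitter,
                  permute_modules_per_mouse = permute_modules_per_mouse)
}
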