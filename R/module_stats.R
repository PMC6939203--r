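#' Monte Carlo enrichment of a gene property across modules
#'
#' Shared machinery of [trg_enrichment()] and
#' [geneset_module_distribution()]: for every module of size s, the null
#' distribution of the member count of `indicator` is built by drawing s
#' genes uniformly without replacement from the clustered universe,
#' `n_perm` times. The empirical p uses the add-one rule
#' `(1 + #{null >= obs}) / (n_perm + 1)` (and `<=` for depletion); the
#' two-sided p doubles the smaller tail and is capped at 1;
#' Benjamini-Hochberg adjusts across modules.
#'
#' @param partition a `gene_module_partition` (or integer labels,
#'   0 = noise).
#' @param indicator logical vector over the same universe.
#' @param n_perm Monte Carlo draws (default 10000).
#' @param seed integer seed.
#' @param alpha significance level used only to set the `direction`
#'   field to `"ns"`.
#' @return data.frame: module, size, observed, expected, p_enriched,
#'   p_depleted, p_two_sided, p_adjusted, direction; the per-module null
#'   samples are in `attr(, "null_samples")`.
#' @export
mc_module_enrichment <- function(partition, indicator, n_perm = 10000,
                                 seed = 1L, alpha = 0.05) {
  labels <- module_labels(partition)
  if (length(indicator) != length(labels))
    stop("indicator and partition cover different universes")
  set.seed(as.integer(seed))
  N <- length(labels)
  mods <- sort(setdiff(unique(labels), 0L))
  nulls <- list()
  rows <- lapply(mods, function(m) {
    s <- sum(labels == m)
    if (s > N) stop("module larger than universe")
    obs <- sum(indicator[labels == m])
    null <- vapply(seq_len(n_perm), function(i)
      sum(indicator[sample.int(N, s)]), numeric(1))
    nulls[[as.character(m)]] <<- null
    p_enr <- (1 + sum(null >= obs)) / (n_perm + 1)
    p_dep <- (1 + sum(null <= obs)) / (n_perm + 1)
    p2 <- min(1, 2 * min(p_enr, p_dep))
    data.frame(module = m, size = s, observed = obs,
               expected = mean(null), p_enriched = p_enr,
               p_depleted = p_dep, p_two_sided = p2)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_two_sided, method = "BH")
  out$direction <- ifelse(out$p_adjusted >= alpha, "ns",
                          ifelse(out$observed > out$expected,
                                 "enriched", "depleted"))
  attr(out, "null_samples") <- nulls
  out
}

module_labels <- function(partition) {
  if (inherits(partition, "gene_module_partition")) partition$labels
  else as.integer(partition)
}

#' TRG enrichment and depletion per gene module
#'
#' Tests whether each module carries more (or fewer) tissue-restricted
#' genes than expected from `n_perm` same-size random draws out of the
#' clustered universe. TRG = union of the AIRE-dependent, AIRE-enhanced
#' and AIRE-independent TRG categories.
#'
#' @param partition a `gene_module_partition` or label vector.
#' @param categories per-gene category character vector.
#' @inheritParams mc_module_enrichment
#' @return As [mc_module_enrichment()].
#' @export
trg_enrichment <- function(partition, categories, n_perm = 10000,
                           seed = 1L, alpha = 0.05) {
  mc_module_enrichment(partition, categories %in% trg_categories(),
                       n_perm = n_perm, seed = seed, alpha = alpha)
}

#' Chromosome composition of gene modules vs a Monte Carlo null
#'
#' For every module x chromosome cell, compares the observed percentage
#' of the module's genes on that chromosome against same-size random
#' modules, one-sided (enrichment). Empirical p-values are BH-adjusted
#' across all cells; cells significant at `alpha` are flagged.
#'
#' @param partition a `gene_module_partition` or label vector.
#' @param chromosomes per-gene chromosome labels.
#' @param n_perm Monte Carlo draws. The default is large because the
#'   smallest attainable BH-adjusted p across an m x c grid of cells is
#'   about (m * c) / n_perm; too few draws make `alpha` unreachable.
#' @param seed integer seed.
#' @param alpha adjusted-p threshold for the `significant` flag
#'   (default 0.01).
#' @return data.frame: module, chromosome, observed_pct, expected_pct,
#'   p_empirical, p_adjusted, significant.
#' @export
chromosome_enrichment <- function(partition, chromosomes, n_perm = 10000,
                                  seed = 1L, alpha = 0.01) {
  labels <- module_labels(partition)
  if (length(chromosomes) != length(labels))
    stop("chromosomes and partition cover different universes")
  if (anyNA(chromosomes)) stop("unknown (NA) chromosome labels")
  set.seed(as.integer(seed))
  chromosomes <- as.character(chromosomes)
  chrs <- sort(unique(chromosomes))
  chr_f <- factor(chromosomes, levels = chrs)
  N <- length(labels)
  mods <- sort(setdiff(unique(labels), 0L))
  out <- list()
  for (m in mods) {
    s <- sum(labels == m)
    obs <- 100 * table(chr_f[labels == m]) / s
    null <- matrix(0, n_perm, length(chrs))
    for (p in seq_len(n_perm))
      null[p, ] <- tabulate(chr_f[sample.int(N, s)], length(chrs))
    null <- 100 * null / s
    p_emp <- vapply(seq_along(chrs), function(ci)
      (1 + sum(null[, ci] >= obs[ci])) / (n_perm + 1), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      module = m, chromosome = chrs, observed_pct = as.numeric(obs),
      expected_pct = colMeans(null), p_empirical = p_emp)
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- stats::p.adjust(res$p_empirical, method = "BH")
  res$significant <- res$p_adjusted < alpha
  res
}

#' Pairwise genomic distance ECDFs of co-expressed genes
#'
#' Distances |start_i - start_j| between all same-chromosome gene pairs,
#' computed for (a) the full gene universe, (b) AIRE-regulated genes
#' only (AIRE-dependent + AIRE-enhanced) and (c) pairs within the same
#' module, with two-sample Kolmogorov-Smirnov comparisons of (b) and
#' (c) against (a).
#'
#' @param gene_meta data.frame with `chromosome`, `position_bp` and
#'   `category` columns.
#' @param partition a `gene_module_partition` or label vector aligned
#'   with `gene_meta` rows.
#' @return List of class `distance_ecdf_set`: per-subset sorted distance
#'   vectors (`all_pairs`, `aire_regulated_pairs`,
#'   `within_module_pairs`) and `ks` (data.frame of comparisons).
#' @export
pairwise_distance_ecdf <- function(gene_meta, partition) {
  labels <- module_labels(partition)
  stopifnot(length(labels) == nrow(gene_meta))
  chr <- as.character(gene_meta$chromosome)
  pos <- as.numeric(gene_meta$position_bp)
  pair_d <- function(sel, same_module = FALSE) {
    d <- numeric(0)
    for (c in unique(chr[sel])) {
      i <- which(sel & chr == c)
      if (length(i) < 2) next
      if (same_module) {
        for (m in setdiff(unique(labels[i]), 0L)) {
          im <- i[labels[i] == m]
          if (length(im) >= 2) d <- c(d, as.numeric(stats::dist(pos[im])))
        }
      } else d <- c(d, as.numeric(stats::dist(pos[i])))
    }
    sort(d)
  }
  all_d <- pair_d(rep(TRUE, length(chr)))
  if (!length(all_d))
    stop("fewer than 2 genes on every chromosome")
  aire <- gene_meta$category %in% c("AIRE-dependent", "AIRE-enhanced")
  aire_d <- pair_d(aire)
  mod_d <- pair_d(labels != 0L, same_module = TRUE)
  ks_row <- function(x, name) {
    if (length(x) < 2)
      return(data.frame(comparison = name, ks_statistic = NA_real_,
                        ks_p = NA_real_, n_pairs = length(x)))
    kt <- suppressWarnings(stats::ks.test(x, all_d))
    data.frame(comparison = name, ks_statistic = unname(kt$statistic),
               ks_p = kt$p.value, n_pairs = length(x))
  }
  structure(list(all_pairs = all_d,
                 aire_regulated_pairs = aire_d,
                 within_module_pairs = mod_d,
                 ks = rbind(ks_row(aire_d, "aire_vs_all"),
                            ks_row(mod_d, "module_vs_all"))),
            class = "distance_ecdf_set")
}

#' Distribution of an arbitrary gene set across modules
#'
#' Applies the Monte Carlo module-composition test to any user-supplied
#' set of gene ids (tissue-specific panels, disease auto-antigen panels,
#' ...). Ids outside the clustered universe are dropped with a warning.
#'
#' @param partition a `gene_module_partition` (needs `gene_id`) or label
#'   vector accompanied by `universe_ids`.
#' @param gene_set character vector of gene ids.
#' @param universe_ids gene ids of the universe when `partition` is a
#'   plain label vector.
#' @inheritParams mc_module_enrichment
#' @return As [mc_module_enrichment()].
#' @export
geneset_module_distribution <- function(partition, gene_set,
                                        n_perm = 10000, seed = 1L,
                                        universe_ids = NULL,
                                        alpha = 0.05) {
  ids <- if (inherits(partition, "gene_module_partition"))
    partition$gene_id else universe_ids
  if (is.null(ids)) stop("gene universe ids are required")
  outside <- setdiff(gene_set, ids)
  if (length(outside))
    warning(length(outside), " gene ids outside the universe dropped")
  inside <- intersect(gene_set, ids)
  if (!length(inside)) stop("gene_set has empty intersection with universe")
  mc_module_enrichment(partition, ids %in% inside,
                       n_perm = n_perm, seed = seed, alpha = alpha)
}
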