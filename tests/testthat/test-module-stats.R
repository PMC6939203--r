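test_that("an all-TRG module reaches the minimal attainable p", {
  n_perm <- 2000
  labels <- c(rep(1, 100), rep(0, 900))
  cats <- c(rep("AIRE-dependent", 100),
            rep(c("AIRE-enhanced", "housekeeping"), 450))
  res <- trg_enrichment(labels, cats, n_perm = n_perm, seed = 1)
  expect_equal(res$p_enriched, 1 / (n_perm + 1))
  expect_equal(res$direction, "enriched")
  expect_equal(res$observed, 100)
  expect_gte(min(res$p_enriched, res$p_depleted), 1 / (n_perm + 1))
})

test_that("Monte Carlo tail matches the exact hypergeometric tail", {
  set.seed(41)
  N <- 600; K <- 240                     # universe, TRG count
  labels <- integer(N)
  labels[sample.int(N, 20)] <- 1L        # one 20-gene module
  cats <- rep("other", N)
  cats[sample.int(N, K)] <- "AIRE-dependent"
  n_perm <- 10000
  res <- trg_enrichment(labels, cats, n_perm = n_perm, seed = 2)
  obs <- res$observed[1]
  p_exact <- phyper(obs - 1, K, N - K, 20, lower.tail = FALSE)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_enriched[1] - p_exact), 3 * se + 2 / n_perm)
})

test_that("null modules give calibrated empirical p-values", {
  set.seed(42)
  N <- 500
  cats <- rep(c("AIRE-dependent", "other"), length.out = N)
  hits <- 0
  n_rep <- 120
  for (r in seq_len(n_rep)) {
    labels <- integer(N)
    labels[sample.int(N, 40)] <- 1L      # random module
    res <- trg_enrichment(labels, cats, n_perm = 400, seed = r)
    if (res$p_two_sided[1] < 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.07)
})

test_that("results are reproducible for identical seeds", {
  labels <- rep(c(0, 1, 2), length.out = 300)
  cats <- rep(c("AIRE-dependent", "other", "other"), 100)
  a <- trg_enrichment(labels, cats, n_perm = 500, seed = 9)
  b <- trg_enrichment(labels, cats, n_perm = 500, seed = 9)
  expect_identical(a, b)
})

test_that("chromosome composition: observed percentages are conserved
           and a single-chromosome module is flagged", {
  set.seed(43)
  n <- 400
  chrom <- paste0("chr", sample.int(20, n, replace = TRUE))
  labels <- integer(n)
  onechr <- which(chrom == "chr1")
  labels[onechr[1:min(20, length(onechr))]] <- 1L
  labels[sample(which(labels == 0), 30)] <- 2L
  res <- chromosome_enrichment(labels, chrom, n_perm = 10000, seed = 3)
  for (m in unique(res$module))
    expect_equal(sum(res$observed_pct[res$module == m]), 100,
                 tolerance = 1e-9)
  expect_true(any(res$significant[res$module == 1 &
                                    res$chromosome == "chr1"]))
  expect_error(chromosome_enrichment(labels, rep(NA, n), 100, 1),
               "chromosome")
})

test_that("uniform chromosome assignment stays below the false-positive
           budget", {
  set.seed(44)
  n_sig <- 0
  for (r in 1:40) {
    n <- 300
    chrom <- paste0("chr", sample.int(10, n, replace = TRUE))
    labels <- integer(n)
    labels[sample.int(n, 30)] <- 1L
    labels[sample(which(labels == 0), 30)] <- 2L
    res <- chromosome_enrichment(labels, chrom, n_perm = 500, seed = r,
                                 alpha = 0.01)
    if (any(res$significant)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 40, 0.05 + 0.05)  # ~95% of datasets clean
})

test_that("distance ECDFs: a contiguous planted module is shifted left,
           identical subsets are not", {
  set.seed(45)
  n <- 300
  gm <- data.frame(gene_id = sprintf("g%d", 1:n),
                   chromosome = paste0("chr",
                                       sample.int(5, n, replace = TRUE)),
                   position_bp = round(runif(n, 1, 1e8)),
                   category = sample(c("AIRE-dependent", "other"), n,
                                     replace = TRUE))
  # module 1: 25 physically adjacent genes inside 1 Mb on chr1
  labels <- integer(n)
  labels[1:25] <- 1L
  gm$chromosome[1:25] <- "chr1"
  gm$position_bp[1:25] <- sort(round(runif(25, 5e7, 5.1e7)))
  res <- pairwise_distance_ecdf(gm, labels)
  ks_mod <- res$ks[res$ks$comparison == "module_vs_all", ]
  expect_lt(ks_mod$ks_p, 0.01)
  expect_lt(median(res$within_module_pairs), median(res$all_pairs))

  # all genes vs themselves: KS statistic 0
  ident <- suppressWarnings(
    stats::ks.test(res$all_pairs, res$all_pairs))
  expect_equal(unname(ident$statistic), 0)

  # randomly assigned modules: small KS statistic
  labels2 <- integer(n)
  labels2[sample.int(n, 150)] <- sample(1:3, 150, replace = TRUE)
  res2 <- pairwise_distance_ecdf(gm, labels2)
  expect_lt(res2$ks$ks_statistic[res2$ks$comparison == "module_vs_all"],
            0.12)
})

test_that("gene-set distribution flags only the module holding the set", {
  set.seed(46)
  n <- 600
  labels <- rep(0:3, length.out = n)
  ids <- sprintf("g%d", 1:n)
  part <- structure(list(labels = labels, gene_id = ids,
                         probabilities = rep(1, n),
                         n_modules = 3L),
                    class = "gene_module_partition")
  set_in_2 <- ids[labels == 2][1:40]
  res <- geneset_module_distribution(part, set_in_2, n_perm = 2000,
                                     seed = 5)
  expect_equal(res$direction[res$module == 2], "enriched")
  expect_true(all(res$direction[res$module != 2] != "enriched"))
  expect_warning(
    geneset_module_distribution(part, c(set_in_2, "nope"), n_perm = 100,
                                seed = 1), "outside")
  expect_error(
    suppressWarnings(
      geneset_module_distribution(part, c("nope"), n_perm = 100,
                                  seed = 1)),
    "empty intersection")
})
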