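test_that("identical config and seed give bit-identical output", {
  cfg <- small_sim_config(seed = 3)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth, b$truth)
  c <- generate_counts(small_sim_config(seed = 4))
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("infeasible module sizes report the deficit", {
  expect_error(
    generate_counts(small_sim_config(n_genes = 50, n_modules = 3,
                                     module_size_range = c(30, 30))),
    "deficit")
})

test_that("planted modules are detected more inside their on-clusters", {
  cfg <- small_sim_config(seed = 5)
  g <- generate_counts(cfg)
  det <- as.matrix(g$matrix$counts > 0)
  cl <- g$truth$cell_cluster_labels
  for (m in seq_len(cfg$n_modules)) {
    genes <- which(g$truth$gene_module_labels == m)
    on_cells <- g$truth$cluster_module_on[cl, m]
    f_on <- mean(det[genes, on_cells])
    f_off <- mean(det[genes, !on_cells])
    expect_gt(f_on, f_off)
  }
})

test_that("without planted structure detection is independent of
           cluster for almost all genes", {
  cfg <- small_sim_config(n_modules = 0, baseline_detect_prob = 0.05,
                          seed = 6)
  g <- generate_counts(cfg)
  det <- as.matrix(g$matrix$counts > 0)
  cl <- g$truth$cell_cluster_labels
  ps <- apply(det, 1, function(row) {
    tab <- table(factor(row, levels = c(FALSE, TRUE)), cl)
    if (any(rowSums(tab) == 0)) return(1)
    suppressWarnings(chisq.test(tab)$p.value)
  })
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("realised sparsity stays near the configured expectation", {
  cfg <- small_sim_config(n_genes = 300, n_modules = 0,
                          baseline_detect_prob = 0.03, seed = 7,
                          n_cells_per_condition = c("unselected" = 1000))
  g <- generate_counts(cfg)
  frac <- Matrix::colSums(g$matrix$counts > 0) / 300
  expect_lt(abs(mean(frac) - 0.03) / 0.03, 0.2)
})

test_that("within-module co-detection beats the cross-module median", {
  cfg <- small_sim_config(seed = 8)
  g <- generate_counts(cfg)
  det <- (g$matrix$counts > 0) * 1
  co <- as.matrix(Matrix::tcrossprod(det)) / ncol(det)
  lab <- g$truth$gene_module_labels
  cross <- co[lab > 0, lab > 0]
  same <- outer(lab[lab > 0], lab[lab > 0], "==")
  diag(same) <- NA
  cross_med <- stats::median(cross[!same], na.rm = TRUE)
  for (m in seq_len(cfg$n_modules)) {
    ww <- co[lab == m, lab == m]
    expect_gt(mean(ww[upper.tri(ww)]), cross_med)
  }
})

test_that("mouse panels share structure across mice and respect cell
           budgets", {
  cfg <- small_sim_config(n_mice = 4, seed = 9)
  g <- generate_mouse_panel(cfg)
  expect_equal(length(unique(g$truth$mouse_ids)), 4L)
  expect_error(generate_mouse_panel(small_sim_config(
    n_mice = 10000, seed = 1)), "exceeds")
  # permuted panels keep per-mouse module structure but decouple mice
  gp <- generate_mouse_panel(cfg, permute_modules_per_mouse = TRUE)
  expect_equal(length(gp$truth$module_permutation), 4L)
})

test_that("sorted-positive cells are enriched in their marker module's
           on-clusters", {
  cfg <- small_sim_config(seed = 10)
  g <- generate_counts(cfg)
  cl <- g$truth$cell_cluster_labels
  cond <- g$truth$condition_labels
  home <- which(g$truth$cluster_module_on[, 1])   # TSPAN8+ marker module
  frac_pos <- mean(cl[cond == "TSPAN8+"] %in% home)
  frac_uns <- mean(cl[cond == "unselected"] %in% home)
  expect_gt(frac_pos, 2 * frac_uns)
})

test_that("synthetic images honour their generating process", {
  # noiseless random image: exactly n local maxima, all inside the mask
  img <- generate_image(128, 128, "random", n_points = 25,
                        spot_radius = 3, noise_sd = 0, seed = 11)
  expect_equal(nrow(img$truth$centroids), 25)
  inside <- vapply(seq_len(25), function(i) {
    p <- round(img$truth$centroids[i, ])
    img$truth$mask[p[1], p[2]]
  }, logical(1))
  expect_true(all(inside))
  expect_identical(img$truth$kind, "random")

  # even image: minimum pairwise spacing respects the inhibition radius
  img_e <- generate_image(128, 128, "even", n_points = 15, seed = 12)
  r_inhib <- 0.7 / sqrt(15 / sum(img_e$truth$mask))
  expect_gte(min(dist(img_e$truth$centroids)), r_inhib)

  # determinism
  img2 <- generate_image(128, 128, "random", n_points = 25,
                         spot_radius = 3, noise_sd = 0, seed = 11)
  expect_identical(img$marker, img2$marker)
})
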