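test_that("gene frequency is the pseudocounted log2 and drops
           single-cell genes", {
  m <- matrix(0, 3, 4)
  m[1, ] <- c(0, 1, 3, 7)       # detected in 3 cells
  m[2, c(1, 3)] <- c(1, 1)      # detected in 2 cells
  m[3, 2] <- 5                  # detected in 1 cell -> dropped
  cm <- toy_count_matrix(m, normalised = TRUE)
  gfr <- gene_frequency(cm)
  expect_equal(rownames(gfr$gf), c("g001", "g002"))
  expect_equal(gfr$dropped, "g003")
  expect_equal(as.numeric(gfr$gf[1, ]), c(0, 1, 2, 3))
})

test_that("the worked inverse-frequency example holds: 25% detection
           gives a ratio of 4", {
  expect_identical(subset_inverse_frequency(100, 25), 4)
  expect_identical(subset_inverse_frequency(400, 100), 4)
  # the regularised form converges to the same ratio for large subsets
  expect_equal(subset_inverse_frequency(4e6, 1e6, regularised = TRUE), 4,
               tolerance = 1e-5)
})

test_that("ICF limits match direct evaluation of the formula", {
  # single condition, W = 1, N = 99, E = 0
  w <- structure(list(W = c(unselected = 1), N = c(unselected = 99),
                      E = matrix(0, 1, 1,
                                 dimnames = list("g1", "unselected")),
                      gene_id = "g1"), class = "icf_weights")
  expect_equal(unname(inverse_cell_frequency(w)["g1"]), log10(99),
               tolerance = 1e-12)

  # gene expressed everywhere, large N: sum of printed weights -> 3.0
  N <- c("TSPAN8+" = 1e6, "TSPAN8-" = 1e6, "GP2+" = 1e6, "GP2-" = 1e6,
         "unselected" = 1e6)
  w2 <- structure(list(W = default_icf_weights(), N = N,
                       E = matrix(N, 1, 5,
                                  dimnames = list("g1", names(N))),
                       gene_id = "g1"), class = "icf_weights")
  expect_equal(unname(inverse_cell_frequency(w2)["g1"]), log10(3),
               tolerance = 1e-4)
})

test_that("rare genes get strictly larger ICF than common ones", {
  # identical per-cell values, detection 5% vs 80%
  N <- c("unselected" = 1000)
  E <- matrix(c(50, 800), 2, 1,
              dimnames = list(c("rare", "common"), "unselected"))
  w <- structure(list(W = c(unselected = 1), N = N, E = E,
                      gene_id = c("rare", "common")),
                 class = "icf_weights")
  icf <- inverse_cell_frequency(w)
  expect_gt(icf["rare"], icf["common"])
})

test_that("gf_icf scales rows and clamps negative ICF", {
  gf <- Matrix::Matrix(matrix(c(1, 2, 0, 3, 4, 5), 3, 2), sparse = TRUE)
  rownames(gf) <- c("a", "b", "c")
  icf <- c(a = 1, b = 1, c = 1)
  expect_equal(as.matrix(gf_icf(gf, icf)), as.matrix(gf),
               ignore_attr = TRUE)
  icf2 <- c(a = 2, b = 0.5, c = 3)
  expect_equal(as.matrix(gf_icf(gf, icf2)),
               naive_gf_icf(as.matrix(gf), icf2), ignore_attr = TRUE)
  expect_error(gf_icf(gf, c(a = 1, b = 1)), "missing")

  # near-saturated detection with sub-unit weights goes negative and is
  # clamped to zero with a flag
  N <- c("GP2+" = 100)
  E <- matrix(99, 1, 1, dimnames = list("g1", "GP2+"))
  w <- structure(list(W = c("GP2+" = 0.02), N = N, E = E,
                      gene_id = "g1"), class = "icf_weights")
  icf3 <- inverse_cell_frequency(w)
  expect_equal(unname(icf3["g1"]), 0)
  expect_true(attr(icf3, "clamped")[1])
  raw <- inverse_cell_frequency(w, clamp_negative = FALSE)
  expect_lt(unname(raw["g1"]), 0)
})

test_that("transform stages match naive loop oracles on random
           matrices", {
  set.seed(31)
  conds <- mtec_conditions()
  for (rep in 1:25) {
    ng <- sample(3:20, 1); nc <- sample(5:10, 1)
    m <- matrix(rpois(ng * nc, 0.8), ng, nc)
    cond <- sample(conds, nc, replace = TRUE)
    cm <- toy_count_matrix(m, conditions = cond, normalised = TRUE)
    gfr <- gene_frequency(cm, min_cells = 0)
    expect_equal(as.matrix(gfr$gf), naive_gene_frequency(m),
                 ignore_attr = TRUE, tolerance = 1e-12)
    w <- icf_weights(cm)
    icf <- inverse_cell_frequency(w, clamp_negative = FALSE)
    expect_equal(as.numeric(icf), naive_icf(w$W, w$N, w$E),
                 tolerance = 1e-12)
    icf_pos <- stats::setNames(pmax(as.numeric(icf), 0), names(icf))
    out <- gf_icf(gfr$gf, icf_pos)
    expect_equal(as.matrix(out),
                 naive_gf_icf(as.matrix(gfr$gf), icf_pos),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("embedding retains rank structure and cosine identities", {
  set.seed(32)
  # rank-1 matrix: trailing singular values vanish
  u <- abs(rnorm(60)); v <- abs(rnorm(30))
  m <- Matrix::Matrix(outer(u, v), sparse = TRUE)
  rownames(m) <- sprintf("g%d", 1:60)
  emb <- embed_genes(m, n_components = 5, perplexity = 5, max_iter = 50)
  expect_lt(emb$singular_values[2] / emb$singular_values[1], 1e-7)

  # duplicated gene rows sit at cosine distance zero
  base <- matrix(rpois(40 * 30, 1), 40, 30)
  base[2, ] <- base[1, ]
  m2 <- Matrix::Matrix(base, sparse = TRUE)
  rownames(m2) <- sprintf("g%d", 1:40)
  emb2 <- embed_genes(m2, n_components = 10, perplexity = 5,
                      max_iter = 50)
  expect_lt(emb2$cosine_distances[1, 2], 1e-10)
  expect_true(all(emb2$cosine_distances >= 0 &
                    emb2$cosine_distances <= 2))
  expect_error(embed_genes(m2, n_components = 100), "fewer genes")
})

test_that("planted orthogonal gene blocks separate in the 2-D map", {
  set.seed(33)
  blockA <- cbind(matrix(rpois(50 * 40, 3), 50, 40),
                  matrix(0, 50, 40))
  blockB <- cbind(matrix(0, 50, 40),
                  matrix(rpois(50 * 40, 3), 50, 40))
  m <- Matrix::Matrix(rbind(blockA, blockB), sparse = TRUE)
  rownames(m) <- sprintf("g%d", 1:100)
  emb <- embed_genes(m, n_components = 10, perplexity = 15,
                     max_iter = 400, seed = 2)
  Z <- emb$coords2d
  within <- mean(dist(Z[1:50, ]))
  between <- mean(as.matrix(dist(Z))[1:50, 51:100])
  expect_gt(between, within)
})

test_that("adjusted mutual information is 1 for relabellings and ~0 for
           independent partitions", {
  set.seed(34)
  a <- sample(1:6, 400, replace = TRUE)
  expect_equal(adjusted_mutual_information(a, a), 1)
  expect_equal(adjusted_mutual_information(a, 7 - a), 1)
  amis <- replicate(30, adjusted_mutual_information(
    sample(1:10, 1000, replace = TRUE),
    sample(1:10, 1000, replace = TRUE)))
  expect_lt(abs(mean(amis)), 0.01)
  expect_true(all(abs(amis) < 0.05))
  expect_error(adjusted_mutual_information(a, a[-1]), "universes")
})
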