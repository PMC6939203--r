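test_that("G is a step function for two points and jumps at the grid
           spacing for a regular lattice", {
  pts <- rbind(c(0, 0), c(3, 4))     # distance 5
  r <- seq(0, 10, by = 0.5)
  g <- as.numeric(g_function(pts, r))
  expect_equal(g[r < 5], rep(0, sum(r < 5)))
  expect_equal(g[r >= 5], rep(1, sum(r >= 5)))

  lattice <- as.matrix(expand.grid(x = seq(0, 90, by = 10),
                                   y = seq(0, 90, by = 10)))
  gl <- as.numeric(g_function(lattice, c(5, 9.99, 10, 15)))
  expect_equal(gl, c(0, 0, 1, 1))
  expect_error(g_function(rbind(c(1, 1)), r), "at least 2")
})

test_that("empirical G of Poisson points tracks the closed form", {
  set.seed(61)
  n <- 2000; side <- 1000
  pts <- cbind(runif(n, 0, side), runif(n, 0, side))
  lambda <- n / side^2
  r <- seq(0, 0.5 / sqrt(lambda), length.out = 40)
  g <- g_function(pts, r)
  theo <- 1 - exp(-lambda * pi * r^2)
  expect_lt(max(abs(g - theo)), 0.05)
})

test_that("G is invariant to point order and rigid rotation", {
  set.seed(62)
  pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  r <- seq(0, 30, length.out = 25)
  g1 <- as.numeric(g_function(pts, r))
  g2 <- as.numeric(g_function(pts[sample(50), ], r))
  th <- pi / 7
  rot <- pts %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  g3 <- as.numeric(g_function(rot, r))
  expect_equal(g1, g2)
  expect_equal(g1, g3, tolerance = 1e-12)
})

test_that("point processes have the expected spacing behaviour", {
  mask <- matrix(TRUE, 120, 120)
  set.seed(63)
  ev <- sample_points_in_mask(mask, 20, "even")
  r_inhib <- 0.7 / sqrt(20 / sum(mask))
  expect_gte(min(dist(ev)), r_inhib)

  nn_mean <- function(p) mean(attr(g_function(p, 1), "nn_distances"))
  m_clu <- replicate(20, nn_mean(
    sample_points_in_mask(mask, 25, "clustered", n_parents = 5)))
  m_ran <- replicate(20, nn_mean(sample_points_in_mask(mask, 25,
                                                       "random")))
  expect_lt(mean(m_clu), mean(m_ran))

  expect_error(sample_points_in_mask(mask, 500, "even",
                                     inhibition_radius = 50),
               "infeasible")
  expect_error(sample_points_in_mask(matrix(FALSE, 10, 10), 3, "random"),
               "too small")
})

test_that("medulla segmentation recovers a planted elliptical blob", {
  img <- generate_image(160, 160, "random", n_points = 5,
                        mask_spec = list(n_blobs = 1,
                                         r_frac = c(0.25, 0.25)),
                        seed = 3)
  # the blob is built so its 0.5-level set is the planted ellipse
  mask <- segment_medulla(img$structure, sigma = 2, threshold = 0.5,
                          erode_radius = 2, dilate_radius = 2)
  planted <- sum(img$truth$mask)
  expect_lt(abs(sum(mask) - planted) / planted, 0.10)

  expect_error(segment_medulla(matrix(0, 50, 50)), "empty mask")

  # robust to faint noise at a fixed threshold
  set.seed(4)
  noisy <- pmin(pmax(img$structure +
                       rnorm(length(img$structure), 0, 0.005), 0), 1)
  m1 <- segment_medulla(img$structure, sigma = 2, threshold = 0.3,
                        erode_radius = 2, dilate_radius = 2)
  m2 <- segment_medulla(noisy, sigma = 2, threshold = 0.3,
                        erode_radius = 2, dilate_radius = 2)
  # blur attenuates the noise ~25-fold; at most a sliver of boundary
  # pixels may flip
  expect_lt(mean(m1 != m2), 1e-3)
})

test_that("noiseless spots are segmented to their planted centroids", {
  img <- generate_image(200, 200, "even", n_points = 25, spot_radius = 3,
                        noise_sd = 0, seed = 7,
                        mask_spec = list(n_blobs = 2,
                                         r_frac = c(0.3, 0.4)))
  seg <- segment_positive_cells(img$marker, sigma = 1)
  expect_equal(nrow(seg$centroids), 25)
  d <- as.matrix(dist(rbind(seg$centroids, img$truth$centroids)))
  cross <- d[1:25, 26:50]
  expect_lt(max(apply(cross, 2, min)), 2)

  empty <- segment_positive_cells(matrix(0, 64, 64))
  expect_equal(nrow(empty$centroids), 0)
})

test_that("watershed splits two overlapping spots", {
  xg <- matrix(1:80, 80, 80); yg <- t(xg)
  disc <- function(cx, cy, r = 6)
    ((xg - cx)^2 + (yg - cy)^2 <= r^2) * 1
  ch <- pmin(disc(36, 40) + disc(45, 40), 1)   # 1.5x radius apart
  seg <- segment_positive_cells(ch, sigma = 1, min_area = 10)
  expect_equal(nrow(seg$centroids), 2)
})

test_that("reference envelopes are ordered as theory predicts", {
  set.seed(65)
  img <- generate_image(140, 140, "random", n_points = 25,
                        mask_spec = list(n_blobs = 2,
                                         r_frac = c(0.3, 0.4)), seed = 9)
  mask <- img$truth$mask
  r <- default_r_grid(mask, 25)
  env_r <- simulate_reference(mask, 25, "random", n_sim = 60,
                              r_grid = r, seed = 1)
  env_c <- simulate_reference(mask, 25, "clustered", n_sim = 60,
                              r_grid = r, seed = 2)
  env_e <- simulate_reference(mask, 25, "even", n_sim = 60, r_grid = r,
                              seed = 3)
  small <- r > 0 & r < stats::median(r)
  expect_gt(mean(env_c$mean_g[small] - env_r$mean_g[small]), 0)
  expect_lt(mean(env_e$mean_g[small] - env_r$mean_g[small]), 0)

  # a random simulation classifies as random most of the time
  set.seed(66)
  hits <- 0
  for (i in 1:20) {
    pts <- sample_points_in_mask(mask, 25, "random")
    cls <- classify_pattern(g_function(pts, r), env_r)
    if (cls == "random") hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("image IO round-trips through TIFF", {
  img <- generate_image(64, 64, "random", n_points = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img$marker, path)
  back <- read_image(path)
  expect_equal(dim(back), dim(img$marker))
  expect_lt(max(abs(back - img$marker)), 0.01)  # 8-bit quantisation
})
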