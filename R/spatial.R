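#' Segment the medullary mask from a structural channel
#'
#' Gaussian low-pass filter, global threshold (Otsu by default), binary
#' erosion then dilation with disc brushes, and removal of components
#' below `min_area`. This is the cytokeratin-mask stage of the spatial
#' pipeline.
#'
#' @param channel single-channel numeric matrix in [0, 1]
#'   (first index = x).
#' @param sigma Gaussian filter sd in pixels (use ~4 for 512x512 marker
#'   channels, ~8 for 1980x1980).
#' @param threshold global threshold; `NULL` uses Otsu's method.
#' @param erode_radius,dilate_radius disc radii in pixels.
#' @param min_area smallest retained component (pixels).
#' @return Logical matrix mask.
#' @export
segment_medulla <- function(channel, sigma = 4, threshold = NULL,
                            erode_radius = 3, dilate_radius = 3,
                            min_area = 100) {
  img <- EBImage::Image(channel)
  b <- EBImage::gblur(img, sigma = sigma)
  th <- if (is.null(threshold)) EBImage::otsu(b, range = c(0, 1))
        else threshold
  bin <- b > th
  if (erode_radius > 0)
    bin <- EBImage::erode(bin, disc_brush(erode_radius))
  if (dilate_radius > 0)
    bin <- EBImage::dilate(bin, disc_brush(dilate_radius))
  lab <- EBImage::bwlabel(bin)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  mask <- matrix(as.integer(lab) %in% keep, nrow(channel), ncol(channel))
  if (!any(mask))
    stop("empty mask after processing; consider overriding the threshold")
  mask
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
}

#' Segment marker-positive cells and compute their centroids
#'
#' Gaussian blur, threshold (Otsu by default), watershed splitting of
#' touching features on the distance map of the binary image (two
#' overlapping spots separate as long as their union keeps a waist),
#' and intensity-weighted first moments as centroids. Features below
#' `min_area` are discarded. An empty channel yields a valid result
#' with zero centroids.
#'
#' @param channel single-channel numeric matrix in [0, 1].
#' @param sigma blur sd in pixels.
#' @param threshold global threshold; `NULL` uses Otsu.
#' @param min_area smallest retained feature (pixels).
#' @param tolerance minimum distance-map dip (pixels) between two
#'   maxima for the watershed to split them.
#' @return List of class `segmentation_result`: `labels` (integer
#'   matrix), `centroids` (n x 2 matrix of (x, y)), `areas`, `params`.
#' @export
segment_positive_cells <- function(channel, sigma = 2, threshold = NULL,
                                   min_area = 4, tolerance = 1) {
  img <- EBImage::Image(channel)
  b <- EBImage::gblur(img, sigma = sigma)
  th <- if (is.null(threshold)) EBImage::otsu(b, range = c(0, 1))
        else threshold
  bin <- b > th
  empty <- structure(list(labels = matrix(0L, nrow(channel),
                                          ncol(channel)),
                          centroids = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL,
                                                             c("x", "y"))),
                          areas = numeric(0),
                          params = list(sigma = sigma, threshold = th,
                                        min_area = min_area)),
                     class = "segmentation_result")
  if (!any(bin)) return(empty)
  lab <- EBImage::watershed(EBImage::distmap(bin), tolerance = tolerance)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_area])
  if (!length(keep)) return(empty)
  mom <- EBImage::computeFeatures.moment(lab, ref = b)
  cent <- unname(mom[keep, c("m.cx", "m.cy"), drop = FALSE])
  dimnames(cent) <- list(NULL, c("x", "y"))
  structure(list(labels = EBImage::imageData(lab),
                 centroids = cent,
                 areas = as.numeric(areas[as.character(keep)]),
                 params = list(sigma = sigma, threshold = th,
                               min_area = min_area)),
            class = "segmentation_result")
}

#' Empirical nearest-neighbour distance distribution G(r)
#'
#' For each point, the Euclidean distance to its nearest neighbour;
#' `G(r)` is the fraction of points whose nearest-neighbour distance is
#' at most r. No analytic edge correction is applied — inference is
#' envelope-based with simulations confined to the same mask, which
#' cancels edge and mask-shape effects.
#'
#' @param points n x 2 matrix of (x, y) coordinates, n >= 2.
#' @param r_grid increasing non-negative distances at which to evaluate.
#' @return Numeric vector `G(r_grid)` in [0, 1] with attribute
#'   `nn_distances`.
#' @export
g_function <- function(points, r_grid) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  g <- vapply(r_grid, function(r) mean(nn <= r), numeric(1))
  attr(g, "nn_distances") <- nn
  g
}

#' Default r grid for a mask and point count
#'
#' Spans `r_min` to 2.5 times the mean Poisson spacing
#' `1/sqrt(n/area)`. A positive `r_min` excludes scales below the
#' segmentation resolution: touching features fuse into one label, so
#' nearest-neighbour distances below the fusion scale are not
#' observable and would bias a classification.
#'
#' @param mask logical mask.
#' @param n point count.
#' @param length grid length.
#' @param r_min smallest evaluated distance (pixels).
#' @return Increasing numeric vector.
#' @export
default_r_grid <- function(mask, n, length = 50, r_min = 0) {
  seq(r_min, max(2.5 / sqrt(n / sum(mask)), r_min + 1),
      length.out = length)
}

#' Simulation envelopes of G(r) for a reference point process
#'
#' Simulates `n_sim` patterns of `n` points inside `mask` under the
#' requested process (see [sample_points_in_mask()]), reduces each to
#' its G-function on `r_grid`, and returns pointwise bands. The default
#' band spans the simulation extremes (the classical global envelope:
#' with 99 simulations a point pattern from the reference process
#' rarely leaves it anywhere), because narrower pointwise quantiles are
#' exited somewhere by most draws of the reference process itself once
#' evaluated on a whole grid.
#'
#' @param mask logical mask.
#' @param n points per simulated pattern.
#' @param kind `"random"`, `"even"` or `"clustered"`.
#' @param n_sim number of simulations (>= 99 recommended for 95% bands).
#' @param r_grid evaluation grid; default [default_r_grid()].
#' @param seed integer seed.
#' @param fuse_radius if positive, simulated points closer than this are
#'   fused to their centroid before G is computed — the same
#'   measurement operator segmentation applies to the observed image,
#'   where touching features become one label.
#' @param band_probs lower/upper quantiles of the band; `c(0, 1)` is
#'   the simulation-extreme (global) envelope.
#' @param ... forwarded to [sample_points_in_mask()].
#' @return List of class `g_envelope`: `r_grid`, `lo`, `hi`, `mean_g`,
#'   `kind`, `g_sims` (matrix r x n_sim).
#' @export
simulate_reference <- function(mask, n, kind = c("random", "even",
                                                 "clustered"),
                               n_sim = 99, r_grid = NULL, seed = 1L,
                               fuse_radius = 0,
                               band_probs = c(0, 1), ...) {
  kind <- match.arg(kind)
  if (is.null(r_grid)) r_grid <- default_r_grid(mask, n)
  set.seed(as.integer(seed))
  sims <- vapply(seq_len(n_sim), function(s) {
    pts <- sample_points_in_mask(mask, n, kind, ...)
    if (fuse_radius > 0) pts <- fuse_points(pts, fuse_radius)
    g_function(pts, r_grid)
  }, numeric(length(r_grid)))
  structure(list(r_grid = r_grid,
                 lo = apply(sims, 1, stats::quantile, band_probs[1],
                            names = FALSE),
                 hi = apply(sims, 1, stats::quantile, band_probs[2],
                            names = FALSE),
                 mean_g = rowMeans(sims),
                 kind = kind,
                 g_sims = sims),
            class = "g_envelope")
}

#' Classify an observed pattern against reference envelopes
#'
#' `"random"` when the observed G lies inside the random-process
#' envelope at >= `coverage` of grid points; otherwise the direction of
#' the first excursion decides: leaving above the band at the smallest
#' excursion radius means tighter nearest neighbours than random
#' (`"clustered"`), leaving below means inhibition (`"even"`);
#' `"indeterminate"` if neither dominates.
#'
#' @param g_observed numeric G values on the envelope's r grid.
#' @param envelopes either a single random-kind `g_envelope` or a named
#'   list with at least `$random`.
#' @param coverage within-band fraction that still counts as random.
#' @return Character scalar: `"random"`, `"clustered"`, `"even"` or
#'   `"indeterminate"`, with attribute `fraction_inside`.
#' @export
classify_pattern <- function(g_observed, envelopes, coverage = 0.95) {
  env <- if (inherits(envelopes, "g_envelope")) envelopes
         else envelopes$random
  if (is.null(env)) stop("a random-process envelope is required")
  inside <- g_observed >= env$lo & g_observed <= env$hi
  frac <- mean(inside)
  out <- if (frac >= coverage) "random" else {
    above <- which(g_observed > env$hi)
    below <- which(g_observed < env$lo)
    first_above <- if (length(above)) min(above) else Inf
    first_below <- if (length(below)) min(below) else Inf
    if (first_above < first_below) "clustered"
    else if (first_below < first_above) "even"
    else "indeterminate"
  }
  attr(out, "fraction_inside") <- frac
  out
}

#' End-to-end spatial randomness test on a two-channel image
#'
#' Segments the medullary mask from the structural channel and the
#' marker-positive cells from the marker channel, keeps centroids inside
#' the mask, computes the observed G-function, simulates the three
#' reference processes inside the same mask, and classifies the pattern.
#'
#' @param marker,structure_channel single-channel numeric matrices
#'   (marker-positive cells and the cytokeratin-like structural signal).
#' @param n_sim simulations per reference kind.
#' @param seed integer seed.
#' @param mask_sigma,mask_erode,mask_dilate medulla segmentation knobs.
#' @param spot_sigma,spot_min_area marker segmentation knobs.
#' @param r_min smallest classified distance; defaults to 4 x
#'   `spot_sigma`, the scale below which touching features fuse and
#'   G is unmeasurable.
#' @param fuse_radius fusion scale applied to reference simulations
#'   (0 = off); `NULL` estimates it as twice the median equivalent
#'   feature radius of the segmentation, for images whose features
#'   merge heavily.
#' @param kinds reference kinds to simulate.
#' @return List of class `g_function_result`: `classification`,
#'   `g_observed`, `r_grid`, `envelopes`, `centroids`, `mask`.
#' @export
spatial_pattern_test <- function(marker, structure_channel,
                                 n_sim = 99, seed = 1L,
                                 mask_sigma = 4, mask_erode = 2,
                                 mask_dilate = 2, spot_sigma = 2,
                                 spot_min_area = 4, r_min = NULL,
                                 fuse_radius = 0,
                                 kinds = c("random", "even",
                                           "clustered")) {
  if (is.null(r_min)) r_min <- 4 * spot_sigma
  mask <- segment_medulla(structure_channel, sigma = mask_sigma,
                          erode_radius = mask_erode,
                          dilate_radius = mask_dilate)
  seg <- segment_positive_cells(marker, sigma = spot_sigma,
                                min_area = spot_min_area)
  cent <- seg$centroids
  ins <- vapply(seq_len(nrow(cent)), function(i) {
    xi <- round(cent[i, 1]); yi <- round(cent[i, 2])
    xi >= 1 && yi >= 1 && xi <= nrow(mask) && yi <= ncol(mask) &&
      mask[xi, yi]
  }, logical(1))
  cent <- cent[ins, , drop = FALSE]
  if (nrow(cent) < 2) stop("fewer than 2 positive cells inside the mask")
  if (is.null(fuse_radius))
    fuse_radius <- 2 * sqrt(stats::median(seg$areas[ins]) / pi)
  r_grid <- default_r_grid(mask, nrow(cent), r_min = r_min)
  g_obs <- g_function(cent, r_grid)
  envs <- lapply(stats::setNames(kinds, kinds), function(k)
    simulate_reference(mask, nrow(cent), k, n_sim = n_sim,
                       r_grid = r_grid, fuse_radius = fuse_radius,
                       seed = sub_seed(seed, paste0("env_", k))))
  structure(list(classification = classify_pattern(g_obs, envs),
                 g_observed = g_obs, r_grid = r_grid,
                 envelopes = envs, centroids = cent, mask = mask),
            class = "g_function_result")
}

#' Write a single-channel image as TIFF or PNG
#'
#' @param channel numeric matrix in [0, 1].
#' @param path output file; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(channel, path) {
  EBImage::writeImage(EBImage::Image(channel), path)
  invisible(path)
}

#' Read a single-channel image from TIFF or PNG
#'
#' Multi-channel files are reduced to their first channel.
#'
#' @param path image file.
#' @return Numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2) d <- d[, , 1]
  as.matrix(d)
}


# replace groups of points within `radius` (single linkage) by their
# centroids — the measurement operator of feature-merging segmentation
fuse_points <- function(pts, radius) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  cl <- stats::cutree(stats::hclust(stats::dist(pts), "single"),
                      h = radius)
  if (max(cl) == n) return(pts)
  out <- vapply(seq_len(max(cl)), function(g)
    colMeans(pts[cl == g, , drop = FALSE]), numeric(2))
  t(out)
}
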