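#' Sample a planar point pattern inside a binary mask
#'
#' Draws `n` points confined to the `TRUE` region of `mask` under one of
#' three generating processes: `"random"` (uniform over mask pixels with
#' sub-pixel jitter), `"even"` (sequential inhibition: uniform proposals
#' accepted only at distance >= `inhibition_radius` from all accepted
#' points), or `"clustered"` (parent-offspring: `n_parents` uniform
#' parents, offspring displaced by isotropic Gaussian of sd
#' `offspring_sd`, rejected until inside the mask).
#'
#' @param mask logical matrix (first index = x, second = y).
#' @param n number of points (>= 1).
#' @param kind `"random"`, `"even"` or `"clustered"`.
#' @param inhibition_radius minimum spacing for `"even"`; default
#'   `0.7 / sqrt(n / area)` with `area = sum(mask)` (pixels).
#' @param n_parents parent count for `"clustered"`.
#' @param offspring_sd offspring displacement sd; default 5% of the mask
#'   bounding-box diagonal.
#' @param max_attempts proposal budget per point before giving up.
#' @return Numeric matrix `n x 2` of (x, y) coordinates.
#' @export
sample_points_in_mask <- function(mask, n, kind = c("random", "even",
                                                    "clustered"),
                                  inhibition_radius = NULL,
                                  n_parents = 5, offspring_sd = NULL,
                                  max_attempts = 200L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  px <- which(mask, arr.ind = TRUE)        # columns: row (x), col (y)
  if (nrow(px) < n) stop("mask area (", nrow(px),
                         " px) too small for ", n, " points")
  jitter2 <- function(m) m + matrix(stats::runif(length(m), -0.5, 0.5),
                                    ncol = 2)
  if (kind == "random") {
    pts <- jitter2(px[sample.int(nrow(px), n, replace = FALSE), ,
                      drop = FALSE])
  } else if (kind == "even") {
    if (is.null(inhibition_radius))
      inhibition_radius <- 0.7 / sqrt(n / nrow(px))
    pts <- matrix(NA_real_, n, 2)
    got <- 0L
    tries <- 0L
    while (got < n) {
      cand <- jitter2(px[sample.int(nrow(px), 1), , drop = FALSE])
      ok <- got == 0L ||
        min(sqrt(rowSums((pts[seq_len(got), , drop = FALSE] -
                            matrix(cand, got, 2, byrow = TRUE))^2))) >=
        inhibition_radius
      if (ok) {
        got <- got + 1L
        pts[got, ] <- cand
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > max_attempts)
          stop("inhibition radius ", signif(inhibition_radius, 3),
               " infeasible: placed ", got, " of ", n, " points")
      }
    }
  } else {
    if (is.null(offspring_sd)) {
      bb <- apply(px, 2, range)
      offspring_sd <- 0.05 * sqrt(sum((bb[2, ] - bb[1, ])^2))
    }
    parents <- px[sample.int(nrow(px), min(n_parents, n)), , drop = FALSE]
    assign_parent <- sample.int(nrow(parents), n, replace = TRUE)
    pts <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (t in seq_len(max_attempts)) {
        cand <- parents[assign_parent[i], ] +
          stats::rnorm(2, 0, offspring_sd)
        xi <- round(cand[1]); yi <- round(cand[2])
        if (xi >= 1 && yi >= 1 && xi <= nrow(mask) && yi <= ncol(mask) &&
            mask[xi, yi]) { pts[i, ] <- cand; break }
      }
      if (anyNA(pts[i, ]))   # stubborn parent near mask edge: redraw it
        pts[i, ] <- jitter2(px[sample.int(nrow(px), 1), , drop = FALSE])
    }
  }
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Generate a synthetic two-channel immunofluorescence image
#'
#' Channel 1 ("structure", the cytokeratin analogue) is a smooth union of
#' elliptical blobs whose 0.5-level set is the true medullary mask.
#' Channel 2 ("marker") contains Gaussian spots centred on points sampled
#' inside the true mask by the requested point process, plus optional
#' Gaussian pixel noise. The exact centroids, mask and process kind are
#' returned as ground truth.
#'
#' @param width,height image size in pixels.
#' @param kind point-process kind passed to [sample_points_in_mask()].
#' @param n_points number of marker-positive cells.
#' @param mask_spec list: `n_blobs`, `r_frac` (length-2 range of blob
#'   semi-axes as a fraction of the short image side).
#' @param spot_radius Gaussian spot sd in pixels.
#' @param noise_sd sd of additive Gaussian noise on both channels.
#' @param seed integer seed.
#' @param ... forwarded to [sample_points_in_mask()].
#' @return List with `structure` and `marker` (numeric matrices in
#'   [0, 1], first index = x) and `truth` (list: `kind`, `centroids`,
#'   `mask`).
#' @export
generate_image <- function(width = 256, height = 256,
                           kind = c("random", "even", "clustered"),
                           n_points = 25,
                           mask_spec = list(n_blobs = 3,
                                            r_frac = c(0.15, 0.3)),
                           spot_radius = 3, noise_sd = 0, seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 1)
  set.seed(as.integer(seed))
  xs <- seq_len(width); ys <- seq_len(height)
  xg <- matrix(xs, width, height)
  yg <- matrix(ys, width, height, byrow = TRUE)
  short <- min(width, height)
  ch1 <- matrix(0, width, height)
  mask <- matrix(FALSE, width, height)
  for (b in seq_len(mask_spec$n_blobs)) {
    cx <- stats::runif(1, 0.25 * width, 0.75 * width)
    cy <- stats::runif(1, 0.25 * height, 0.75 * height)
    a <- stats::runif(1, mask_spec$r_frac[1], mask_spec$r_frac[2]) * short
    bax <- stats::runif(1, mask_spec$r_frac[1], mask_spec$r_frac[2]) * short
    th <- stats::runif(1, 0, pi)
    dx <- xg - cx; dy <- yg - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    q <- (u / a)^2 + (v / bax)^2        # 1 on the ellipse boundary
    ch1 <- ch1 + exp(-q * log(2))       # value 0.5 at the boundary
    mask <- mask | (q <= 1)
  }
  ch1 <- pmin(ch1, 1)

  pts <- sample_points_in_mask(mask, n_points, kind, ...)
  ch2 <- matrix(0, width, height)
  for (i in seq_len(nrow(pts))) {
    d2 <- (xg - pts[i, 1])^2 + (yg - pts[i, 2])^2
    ch2 <- ch2 + exp(-d2 / (2 * spot_radius^2))
  }
  ch2 <- pmin(ch2, 1)
  if (noise_sd > 0) {
    ch1 <- pmin(pmax(ch1 + stats::rnorm(length(ch1), 0, noise_sd), 0), 1)
    ch2 <- pmin(pmax(ch2 + stats::rnorm(length(ch2), 0, noise_sd), 0), 1)
  }
  list(structure = ch1, marker = ch2,
       truth = list(kind = kind, centroids = pts, mask = mask))
}
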