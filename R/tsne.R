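#' Exact t-SNE on a precomputed distance matrix
#'
#' A direct implementation of t-distributed stochastic neighbour
#' embedding for precomputed distances: input affinities are Gaussian
#' kernels on squared distances with per-point bandwidths calibrated to
#' the target perplexity by bisection; the low-dimensional map uses the
#' Student-t kernel, gradient descent with momentum, adaptive gains and
#' early exaggeration. Exact (dense) gradients are used, which is the
#' right trade-off at the few-thousand-point scale this package embeds.
#'
#' @param D symmetric non-negative distance matrix (e.g. cosine
#'   distances of SVD left vectors).
#' @param dims output dimensionality (2 for the gene map).
#' @param perplexity effective neighbour count; must satisfy
#'   `3 * perplexity < n - 1`.
#' @param max_iter gradient iterations.
#' @param eta learning rate.
#' @param exaggeration early-exaggeration factor (first
#'   `exaggeration_iter` iterations).
#' @param exaggeration_iter iterations of the exaggeration phase.
#' @param seed integer seed for the random initial map.
#' @return Numeric matrix n x `dims`.
#' @export
tsne_embed <- function(D, dims = 2, perplexity = 50, max_iter = 1000,
                       eta = 200, exaggeration = 12,
                       exaggeration_iter = 250, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D)) stop("D must be square")
  if (3 * perplexity >= n - 1)
    perplexity <- max(2, floor((n - 1) / 3) - 1)
  P <- perplexity_affinities(D^2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P / sum(P), .Machine$double.eps)

  set.seed(as.integer(seed))
  Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  tsne_iterate_cpp(P, Y, as.integer(max_iter), eta, exaggeration,
                   as.integer(exaggeration_iter))
}

# per-row Gaussian bandwidth calibration: find beta_i so the conditional
# distribution over squared distances has entropy log(perplexity)
perplexity_affinities <- function(D2, perplexity, tol = 1e-5,
                                  max_tries = 50) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (t in seq_len(max_tries)) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) { H <- 0; p[] <- 0 }
      else {
        H <- log(s) + beta * sum(di * p) / s
        p <- p / s
      }
      if (abs(H - target) < tol) break
      if (H > target) {           # too flat: increase beta
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
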