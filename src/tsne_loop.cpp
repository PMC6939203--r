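// Gradient-descent phase of exact t-SNE. The input affinity matrix P is
// prepared in R (perplexity calibration); this loop only iterates the
// Student-t map with momentum, adaptive gains and early exaggeration.
// The Student-t kernel and the (P - Q) * num product are evaluated over
// the upper triangle only and mirrored, since both are symmetric.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat tsne_iterate_cpp(const arma::mat& P, arma::mat Y, int max_iter,
                           double eta, double exaggeration,
                           int exaggeration_iter) {
  const arma::uword n = Y.n_rows;
  const arma::uword d = Y.n_cols;
  const double eps = 2.2e-16;
  arma::mat dY(n, d, arma::fill::zeros);
  arma::mat gains(n, d, arma::fill::ones);
  arma::mat Pe = P * exaggeration;
  arma::mat num(n, n, arma::fill::zeros);
  arma::mat L(n, n, arma::fill::zeros);

  for (int iter = 1; iter <= max_iter; ++iter) {
    const arma::mat& Pcur = (iter <= exaggeration_iter) ? Pe : P;
    arma::mat G = Y * Y.t();
    double Z = 0.0;
    for (arma::uword j = 1; j < n; ++j) {
      const double gjj = G(j, j);
      double* numj = num.colptr(j);
      const double* Gj = G.colptr(j);
      for (arma::uword i = 0; i < j; ++i) {
        double v = 1.0 / (1.0 + G(i, i) + gjj - 2.0 * Gj[i]);
        numj[i] = v;
        Z += v;
      }
    }
    Z *= 2.0;
    arma::vec rs(n, arma::fill::zeros);
    for (arma::uword j = 1; j < n; ++j) {
      double* Lj = L.colptr(j);
      const double* numj = num.colptr(j);
      const double* Pj = Pcur.colptr(j);
      for (arma::uword i = 0; i < j; ++i) {
        double q = numj[i] / Z;
        if (q < eps) q = eps;
        double l = (Pj[i] - q) * numj[i];
        Lj[i] = l;
        L(j, i) = l;
        rs(i) += l;
        rs(j) += l;
      }
    }
    arma::mat grad = 4.0 * (Y.each_col() % rs - L * Y);

    double momentum = (iter <= exaggeration_iter) ? 0.5 : 0.8;
    for (arma::uword i = 0; i < n * d; ++i) {
      bool same = (grad(i) > 0) == (dY(i) > 0);
      gains(i) = same ? std::max(gains(i) * 0.8, 0.01) : gains(i) + 0.2;
      dY(i) = momentum * dY(i) - eta * gains(i) * grad(i);
      Y(i) += dY(i);
    }
    arma::rowvec mu = arma::mean(Y, 0);
    Y.each_row() -= mu;
  }
  return Y;
}
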