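// SOM training hot loop. Randomness (presentation order, initialization)
// and schedules are computed in R; this loop is fully deterministic.
//
// Weights are handled column-per-neuron (d x K) for contiguous access;
// squared weight norms are maintained incrementally from the update
// algebra and refreshed periodically against floating-point drift.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// weights: neurons x d (modified copy returned in the same orientation)
// X: n x d training spectra
// order: presentation order, 0-based indices into rows of X, length = steps
// D2: neurons x neurons squared hex-layout distances
// alpha, sigma: per-step learning rate and neighbourhood radius
// epoch_len: presentations per epoch (for the running QE trace)
// [[Rcpp::export]]
Rcpp::List som_train_cpp(const arma::mat& weights, const arma::mat& X,
                         const arma::ivec& order, const arma::mat& D2,
                         const arma::vec& alpha, const arma::vec& sigma,
                         const int epoch_len) {
  arma::mat W = weights.t();            // d x K
  const arma::mat Xt = X.t();           // d x n
  const arma::uword steps = order.n_elem;
  const arma::uword K = W.n_cols;
  const arma::uword n_epochs = (steps + epoch_len - 1) / epoch_len;
  arma::vec qe_sum(n_epochs, arma::fill::zeros);
  arma::uvec qe_n(n_epochs, arma::fill::zeros);

  arma::vec xnorm(Xt.n_cols);
  for (arma::uword i = 0; i < Xt.n_cols; ++i) xnorm(i) = arma::norm(Xt.col(i), 2);
  arma::vec wsq = arma::sum(arma::square(W), 0).t(); // per-neuron ||w||^2

  for (arma::uword t = 0; t < steps; ++t) {
    if (t % 512 == 0) wsq = arma::sum(arma::square(W), 0).t();
    const arma::uword r = (arma::uword)order(t);
    const arma::vec x = Xt.col(r);

    // cosine-similarity BMU (first occurrence on exact ties)
    const arma::vec dots = W.t() * x;
    double best = -2.0;
    arma::uword b = 0;
    for (arma::uword k = 0; k < K; ++k) {
      const double wn = std::sqrt(wsq(k));
      const double s = (wn > 0.0 && xnorm(r) > 0.0)
        ? dots(k) / (wn * xnorm(r)) : -1.0;
      if (s > best) { best = s; b = k; }
    }
    const arma::uword e = t / (arma::uword)epoch_len;
    qe_sum(e) += 1.0 - best;
    qe_n(e) += 1;

    const double a = alpha(t);
    const double s2 = 2.0 * sigma(t) * sigma(t);
    const double xsq = xnorm(r) * xnorm(r);
    for (arma::uword k = 0; k < K; ++k) {
      const double h = std::exp(-D2(k, b) / s2);
      const double ah = a * h;
      if (ah < 1e-9) continue; // negligible update far from the BMU
      const double keep = 1.0 - ah;
      // ||w'||^2 from the convex-update algebra, before touching w
      wsq(k) = keep * keep * wsq(k) + 2.0 * keep * ah * dots(k) + ah * ah * xsq;
      W.col(k) = keep * W.col(k) + ah * x;
    }
  }

  arma::vec qe(n_epochs);
  for (arma::uword e = 0; e < n_epochs; ++e) {
    qe(e) = qe_n(e) > 0 ? qe_sum(e) / qe_n(e) : NA_REAL;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = W.t(),
                            Rcpp::Named("qe_trace") = qe);
}
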