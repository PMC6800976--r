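// Exact t-SNE (van der Maaten & Hinton 2008) for small point sets.
// Quadratic in the number of points; the window counts handled here
// (g on the order of a few hundred) make the O(g^2) kernel cheap, so
// no Barnes-Hut approximation is needed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::rowvec;

// Pairwise squared Euclidean distances between rows of X.
static mat squared_distances(const mat& X) {
  vec sq = arma::sum(arma::square(X), 1);
  mat D = arma::repmat(sq, 1, X.n_rows) + arma::repmat(sq.t(), X.n_rows, 1)
    - 2.0 * (X * X.t());
  D.diag().zeros();
  D.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return D;
}

// Row-conditional affinities p_{j|i} with per-row precision tuned by
// bisection so each row's perplexity matches the target.
static mat conditional_affinities(const mat& D2, const double perplexity,
                                  const double tol = 1e-5,
                                  const int max_tries = 60) {
  const arma::uword n = D2.n_rows;
  const double log_perp = std::log(perplexity);
  mat P(n, n, arma::fill::zeros);

  for (arma::uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_min = -arma::datum::inf, beta_max = arma::datum::inf;
    rowvec Di = D2.row(i);
    rowvec Pi(n, arma::fill::zeros);

    for (int tries = 0; tries < max_tries; ++tries) {
      Pi = arma::exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = arma::accu(Pi);
      if (sumP < 1e-300) sumP = 1e-300;
      // Shannon entropy H = log(sumP) + beta * <D>_P
      const double H = std::log(sumP) + beta * arma::dot(Di, Pi) / sumP;
      Pi /= sumP;
      const double diff = H - log_perp;
      if (std::fabs(diff) < tol) break;
      if (diff > 0) {  // entropy too high -> sharpen
        beta_min = beta;
        beta = std::isinf(beta_max) ? beta * 2.0 : (beta + beta_max) / 2.0;
      } else {
        beta_max = beta;
        beta = std::isinf(beta_min) ? beta / 2.0 : (beta + beta_min) / 2.0;
      }
    }
    P.row(i) = Pi;
  }
  return P;
}

// [[Rcpp::export]]
arma::mat tsne_embed_cpp(const arma::mat& X, const arma::mat& Y0,
                         const double perplexity, const int n_iter,
                         const double eta = 200.0,
                         const double exaggeration = 12.0,
                         const int exaggeration_iter = 100,
                         const int momentum_switch = 250) {
  const arma::uword n = X.n_rows;

  mat P = conditional_affinities(squared_distances(X), perplexity);
  P = (P + P.t()) / (2.0 * static_cast<double>(n));
  P.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });

  mat Y = Y0;
  mat dY(n, 2, arma::fill::zeros);
  mat gains(n, 2, arma::fill::ones);
  mat grad(n, 2);
  mat W(n, n);
  const double min_gain = 0.01;

  for (int iter = 0; iter < n_iter; ++iter) {
    const double ex = (iter < exaggeration_iter) ? exaggeration : 1.0;
    const double momentum = (iter < momentum_switch) ? 0.5 : 0.8;

    // Student-t kernel in the embedding space; explicit pair loops keep the
    // per-iteration cost at a handful of flops per (i, j) with no temporaries.
    double sumW = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      for (arma::uword j = i + 1; j < n; ++j) {
        const double d0 = Y(i, 0) - Y(j, 0);
        const double d1 = Y(i, 1) - Y(j, 1);
        const double w = 1.0 / (1.0 + d0 * d0 + d1 * d1);
        W(i, j) = w;
        sumW += w;
      }
    }
    sumW *= 2.0;
    if (sumW < 1e-300) sumW = 1e-300;
    const double inv_sumW = 1.0 / sumW;

    // grad_i = 4 * sum_j (ex*p_ij - q_ij) w_ij (y_i - y_j)
    grad.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      for (arma::uword j = i + 1; j < n; ++j) {
        const double w = W(i, j);
        const double l = (ex * P(i, j) - w * inv_sumW) * w;
        const double g0 = l * (Y(i, 0) - Y(j, 0));
        const double g1 = l * (Y(i, 1) - Y(j, 1));
        grad(i, 0) += g0; grad(i, 1) += g1;
        grad(j, 0) -= g0; grad(j, 1) -= g1;
      }
    }
    grad *= 4.0;

    for (arma::uword k = 0; k < n * 2; ++k) {
      const bool same_sign = (grad(k) > 0.0) == (dY(k) > 0.0);
      gains(k) = same_sign ? gains(k) * 0.8 : gains(k) + 0.2;
      if (gains(k) < min_gain) gains(k) = min_gain;
    }
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= arma::mean(Y, 0);
  }
  return Y;
}
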