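// Full-batch RPROP- training core for the small feedforward summary
// networks. Hidden layers use the symmetric Elliott activation
// s*x/(1+|s*x|); the output uses the (0,1) variant. Dropout masks are
// drawn from R's RNG (unif_rand) in the same order as the R reference
// backend, so both backends are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat elliott_sym(const arma::mat& z, double s) {
  return (s * z) / (1.0 + arma::abs(s * z));
}
static inline arma::mat elliott_sym_d(const arma::mat& z, double s) {
  arma::mat den = 1.0 + arma::abs(s * z);
  return s / (den % den);
}
static inline arma::mat elliott_pos(const arma::mat& z, double s) {
  return 0.5 * elliott_sym(z, s) + 0.5;
}
static inline arma::mat elliott_pos_d(const arma::mat& z, double s) {
  return 0.5 * elliott_sym_d(z, s);
}

// [[Rcpp::export(name = ".rprop_train_cpp")]]
List rprop_train_cpp(List W0, const arma::mat& X, const arma::vec& y,
                     double slope, double dropout, int max_iter,
                     double target_error) {
  RNGScope rngScope;
  const int L = W0.size();
  std::vector<arma::mat> W(L), step(L), prev_sign(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    step[l] = arma::mat(W[l].n_rows, W[l].n_cols, arma::fill::value(0.1));
    prev_sign[l] = arma::mat(W[l].n_rows, W[l].n_cols, arma::fill::zeros);
  }
  const double eta_plus = 1.2, eta_minus = 0.5;
  const double step_max = 50.0, step_min = 1e-6;
  const int n = X.n_rows;

  std::vector<arma::mat> Z(L), A(L);
  std::vector<arma::rowvec> mask(L - 1);
  double mse = arma::datum::inf;
  int it = 0;
  bool bad = false;

  while (it < max_iter) {
    ++it;
    // dropout masks, layer by layer, unit by unit (R RNG order)
    for (int l = 0; l < L - 1; ++l) {
      int h = W[l].n_cols;
      mask[l] = arma::rowvec(h, arma::fill::ones);
      if (dropout > 0) {
        for (int j = 0; j < h; ++j)
          mask[l](j) = (unif_rand() >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
      }
    }
    // forward
    const arma::mat* a = &X;
    for (int l = 0; l < L; ++l) {
      int nin = W[l].n_rows - 1;
      Z[l] = (*a) * W[l].rows(0, nin - 1);
      Z[l].each_row() += W[l].row(nin);
      if (l < L - 1) {
        A[l] = elliott_sym(Z[l], slope);
        A[l].each_row() %= mask[l];
      } else {
        A[l] = elliott_pos(Z[l], slope);
      }
      a = &A[l];
    }
    arma::vec resid = A[L - 1].col(0) - y;
    mse = arma::dot(resid, resid) / n;
    if (!std::isfinite(mse)) { bad = true; break; }
    if (mse <= target_error) break;
    // backward
    arma::mat delta = (2.0 / n) * resid % elliott_pos_d(Z[L - 1], slope);
    for (int l = L - 1; l >= 0; --l) {
      const arma::mat& a_prev = (l == 0) ? X : A[l - 1];
      arma::mat G = arma::join_cols(a_prev.t() * delta,
                                    arma::sum(delta, 0));
      if (l > 0) {
        int nin = W[l].n_rows - 1;
        delta = (delta * W[l].rows(0, nin - 1).t()) %
          elliott_sym_d(Z[l - 1], slope);
        delta.each_row() %= mask[l - 1];
      }
      // RPROP- update for this layer
      arma::mat sgn = arma::sign(G);
      arma::mat prod = sgn % prev_sign[l];
      arma::umat up = prod > 0, down = prod < 0;
      step[l].elem(arma::find(up)) *= eta_plus;
      step[l].elem(arma::find(down)) *= eta_minus;
      step[l] = arma::clamp(step[l], step_min, step_max);
      W[l] -= sgn % step[l];
      prev_sign[l] = sgn;
    }
  }

  List Wout(L);
  for (int l = 0; l < L; ++l) Wout[l] = W[l];
  return List::create(_["W"] = Wout, _["mse"] = mse,
                      _["iterations"] = it, _["diverged"] = bad);
}
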