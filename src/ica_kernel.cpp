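// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Euler-Maruyama kernel for the Bayesian ICA posterior over W (m x m),
// state vec(W) column-major, all five sampler kinds. Uses the Kronecker
// structure of the metric B = (I + W'W) (x) I_m: for any m x m matrix G,
//   B  vec(G) = vec(G (I + W'W))
//   J  vec(G) = vec(C0 G - G C0)          (J = (I (x) C0) + (C0 (x) I))
//   div B     = (m + 1) vec(W)
//   div C     = vec((m+1) C0 W - (m/2) W C0)
// with C0 already carrying any rescaling of J. Noise and minibatch index
// draws happen in R on the chain's streams and are passed in.

// kind codes: 0 = LD, 1 = RM, 2 = Irr, 3 = RMIrr, 4 = GiIrr

// [[Rcpp::export]]
List ica_chain_cpp(int kind, const arma::mat& W0, double h, double beta,
                   const arma::mat& C0, double lambda, int N,
                   const arma::mat& X, const arma::mat& noise,
                   const IntegerMatrix& sub_ids, bool use_sg,
                   bool store_states) {
  const int m = W0.n_rows;
  const int d = m * m;
  const int K = noise.n_rows;
  if ((int)noise.n_cols != d) stop("noise must have m^2 columns");
  if (use_sg && sub_ids.nrow() != K) stop("sub_ids must have K rows");

  arma::mat W = W0;
  NumericVector phi1(K), phi2(K), phi3(K);
  NumericMatrix states;
  if (store_states) states = NumericMatrix(K + 1, d);
  const double sq2bh = std::sqrt(2.0 * beta * h);
  const arma::mat Im = arma::eye(m, m);
  const bool metric_kind = (kind == 1 || kind == 3 || kind == 4);
  const int nsub = use_sg ? sub_ids.ncol() : N;
  const double scale = (double)N / (double)nsub;

  auto record_state = [&](int row) {
    for (int j = 0; j < d; ++j) states(row, j) = W(j % m, j / m);
  };
  if (store_states) record_state(0);

  arma::mat Xs(m, nsub);
  for (int k = 0; k < K; ++k) {
    const double s = arma::accu(W);
    phi1[k] = s;
    phi2[k] = arma::accu(W % W);
    phi3[k] = s * s;

    // gradient matrix f(W) = N (W')^-1 - (N/n) sum tanh(y/2) x' - lambda W
    arma::mat Wti;
    bool ok = arma::inv(Wti, W.t());
    if (!ok || !Wti.is_finite())
      stop("singular de-mixing matrix W at step %d", k + 1);
    arma::mat G = (double)N * Wti - lambda * W;
    if (N > 0) {
      if (use_sg) {
        for (int j = 0; j < nsub; ++j)
          Xs.col(j) = X.col(sub_ids(k, j) - 1);
        G -= scale * (arma::tanh(0.5 * (W * Xs)) * Xs.t());
      } else {
        G -= arma::tanh(0.5 * (W * X)) * X.t();
      }
    }

    arma::mat b(m, m);
    switch (kind) {
    case 0: b = beta * G; break;
    case 2: b = beta * G + (C0 * G - G * C0); break;
    default: {
      const arma::mat IS = Im + W.t() * W;
      const arma::mat BG = G * IS;
      if (kind == 1) {
        b = beta * BG + beta * (m + 1) * W;
      } else if (kind == 3) {
        b = beta * BG + (C0 * G - G * C0) + beta * (m + 1) * W;
      } else { // GiIrr
        const arma::mat JG = C0 * G - G * C0;
        b = beta * BG + 0.5 * ((C0 * BG - BG * C0) + JG * IS) +
          beta * (m + 1) * W + (m + 1) * (C0 * W) - 0.5 * m * (W * C0);
      }
    }
    }

    // noise: sqrt(2 beta h) Xi for LD/Irr, sqrt(2 beta h) Xi R with
    // R = (I + W'W)^(1/2) for the metric kinds ((R (x) I) vec(Xi) = vec(Xi R))
    arma::mat Xi(m, m);
    for (int j = 0; j < d; ++j) Xi(j % m, j / m) = noise(k, j);
    arma::mat nz;
    if (metric_kind) {
      arma::mat R;
      if (!arma::sqrtmat_sympd(R, Im + W.t() * W))
        stop("metric square root failed at step %d", k + 1);
      nz = sq2bh * (Xi * R);
    } else {
      nz = sq2bh * Xi;
    }

    W += h * b + nz;
    if (!W.is_finite())
      stop("non-finite state at step %d", k + 1);
    if (store_states) record_state(k + 1);
  }

  List out = List::create(_["phi1"] = phi1, _["phi2"] = phi2,
                          _["phi3"] = phi3,
                          _["final_state"] = NumericVector(W.begin(), W.end()));
  if (store_states) out["states"] = states;
  return out;
}
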