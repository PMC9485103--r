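#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama kernels for the two constant-coefficient hot paths: the
// 2-D normal-parameters target (all five sampler kinds) and affine-drift
// chains (every kind on a linear-Gaussian target, and Ornstein-Uhlenbeck
// test processes). Noise and per-step minibatch sums are drawn in R from
// the chain's RNG streams and passed in, so these kernels are purely
// deterministic and reproduce the generic R stepper's trajectories.

// kind codes: 0 = LD, 1 = RM, 2 = Irr, 3 = RMIrr, 4 = GiIrr

// [[Rcpp::export]]
List np_chain_cpp(int kind, double mu0, double sigma0, double h, double beta,
                  double delta, int N, NumericVector S1, NumericVector S2,
                  double nsub, NumericMatrix noise, bool store_states) {
  const int K = noise.nrow();
  if (S1.size() != K || S2.size() != K)
    stop("S1/S2 must have one entry per step");
  NumericVector phi1(K), phi2(K);
  NumericMatrix states;
  if (store_states) states = NumericMatrix(K + 1, 2);

  double mu = mu0, sigma = sigma0;
  const double sqbh = std::sqrt(2.0 * beta * h);
  const double scale = (double)N / nsub;

  if (store_states) { states(0, 0) = mu; states(0, 1) = sigma; }

  for (int k = 0; k < K; ++k) {
    phi1[k] = mu + sigma;
    phi2[k] = mu * mu + sigma * sigma;

    const double s2 = sigma * sigma;
    const double m1 = scale * (S1[k] - nsub * mu);
    const double m2 = scale * (S2[k] - 2.0 * mu * S1[k] + nsub * mu * mu);
    const double g1 = m1 / s2;
    const double g2 = -(double)N / sigma + m2 / (s2 * sigma);

    double b1, b2, n1, n2;
    const double xi1 = noise(k, 0), xi2 = noise(k, 1);
    switch (kind) {
    case 0: // LD
      b1 = beta * g1;
      b2 = beta * g2;
      n1 = sqbh * xi1; n2 = sqbh * xi2;
      break;
    case 2: // Irr: (beta I + J) g, J = delta [[0,1],[-1,0]]
      b1 = beta * g1 + delta * g2;
      b2 = -delta * g1 + beta * g2;
      n1 = sqbh * xi1; n2 = sqbh * xi2;
      break;
    default: { // metric kinds: B = (sigma^2/N) diag(1, 1/2)
      const double b11 = s2 / N;
      const double b22 = s2 / (2.0 * N);
      const double divB2 = sigma / N;
      const double sfac = sigma / std::sqrt((double)N);
      if (kind == 1) { // RM
        b1 = beta * b11 * g1;
        b2 = beta * (b22 * g2 + divB2);
      } else if (kind == 3) { // RMIrr
        b1 = beta * b11 * g1 + delta * g2;
        b2 = -delta * g1 + beta * b22 * g2 + beta * divB2;
      } else { // GiIrr: C = (3 sigma^2 / 4N) J, div C = (3 delta sigma / 2N, 0)
        const double c12 = 3.0 * s2 * delta / (4.0 * N);
        b1 = beta * b11 * g1 + c12 * g2 + 3.0 * delta * sigma / (2.0 * N);
        b2 = -c12 * g1 + beta * b22 * g2 + beta * divB2;
      }
      n1 = sqbh * sfac * xi1;
      n2 = sqbh * sfac * xi2 / std::sqrt(2.0);
    }
    }

    mu += h * b1 + n1;
    sigma += h * b2 + n2;
    if (!(sigma > 0.0) || !std::isfinite(mu) || !std::isfinite(sigma))
      stop("sigma <= 0 or non-finite state at step %d (mu = %g, sigma = %g)",
           k + 1, mu, sigma);
    if (store_states) { states(k + 1, 0) = mu; states(k + 1, 1) = sigma; }
  }

  List out = List::create(_["phi1"] = phi1, _["phi2"] = phi2,
                          _["final_state"] = NumericVector::create(mu, sigma));
  if (store_states) out["states"] = states;
  return out;
}

// Affine-drift chain: theta' = theta + h (G theta + o_k) + sqrt(h) L xi_k.
// offsets: either a 1 x d matrix (constant offset) or K x d (per-step, e.g.
// stochastic-gradient data terms precomputed in R).
// [[Rcpp::export]]
List affine_chain_cpp(NumericMatrix G, NumericMatrix offsets, NumericMatrix L,
                      double h, NumericVector theta0, NumericMatrix noise,
                      bool store_states) {
  const int d = G.nrow();
  const int K = noise.nrow();
  if (G.ncol() != d || L.nrow() != d || L.ncol() != d || noise.ncol() != d ||
      theta0.size() != d)
    stop("dimension mismatch in affine_chain_cpp");
  const bool const_off = offsets.nrow() == 1;
  if (!const_off && offsets.nrow() != K)
    stop("offsets must have 1 or K rows");

  NumericVector phi1(K), phi2(K);
  NumericMatrix states;
  if (store_states) states = NumericMatrix(K + 1, d);
  std::vector<double> th(theta0.begin(), theta0.end()), b(d), nz(d);
  const double sqh = std::sqrt(h);
  if (store_states)
    for (int j = 0; j < d; ++j) states(0, j) = th[j];

  for (int k = 0; k < K; ++k) {
    double s = 0.0, s2 = 0.0;
    for (int j = 0; j < d; ++j) { s += th[j]; s2 += th[j] * th[j]; }
    phi1[k] = s; phi2[k] = s2;

    const int orow = const_off ? 0 : k;
    for (int i = 0; i < d; ++i) {
      double acc = offsets(orow, i);
      double nacc = 0.0;
      for (int j = 0; j < d; ++j) {
        acc += G(i, j) * th[j];
        nacc += L(i, j) * noise(k, j);
      }
      b[i] = acc; nz[i] = nacc;
    }
    for (int i = 0; i < d; ++i) {
      th[i] += h * b[i] + sqh * nz[i];
      if (!std::isfinite(th[i]))
        stop("non-finite state at step %d", k + 1);
    }
    if (store_states)
      for (int j = 0; j < d; ++j) states(k + 1, j) = th[j];
  }

  List out = List::create(_["phi1"] = phi1, _["phi2"] = phi2,
                          _["final_state"] = NumericVector(th.begin(), th.end()));
  if (store_states) out["states"] = states;
  return out;
}
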