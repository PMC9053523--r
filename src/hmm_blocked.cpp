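#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joint draw of hidden state sequences from their exact conditional
// posterior given transition matrix and emission parameters, via backward
// message passing followed by forward sampling.  Messages are kept in
// linear space with per-step normalization (scaled forward-backward);
// emission likelihoods are row-scaled by their per-step maximum before
// exponentiation, so the draw is exact and numerically stable.
// Uniform variates are supplied by the caller so the draw is governed by
// R's RNG stream.
//
// loglik:      T_total x L matrix of per-step per-state emission log densities
// Pi:          L x L transition matrix (rows sum to 1)
// pi0:         length-L initial distribution (one chain start per run)
// run_start:   0-based start index of each contiguous run in loglik
// run_length:  length (steps) of each run
// u:           T_total uniforms in (0,1), one per step
//
// returns: integer vector of 1-based state labels, length T_total
// [[Rcpp::export]]
IntegerVector cpp_sample_states(const NumericMatrix& loglik,
                                const NumericMatrix& Pi,
                                const NumericVector& pi0,
                                const IntegerVector& run_start,
                                const IntegerVector& run_length,
                                const NumericVector& u) {
  const int L = loglik.ncol();
  const int Ttot = loglik.nrow();
  if (Pi.nrow() != L || Pi.ncol() != L || pi0.size() != L)
    stop("dimension mismatch between loglik, Pi and pi0");
  if (u.size() != Ttot) stop("need one uniform per step");

  // row-scaled emission likelihoods, column-major like R
  std::vector<double> lik((size_t)Ttot * L);
  for (int t = 0; t < Ttot; ++t) {
    double mx = -INFINITY;
    for (int k = 0; k < L; ++k) if (loglik(t, k) > mx) mx = loglik(t, k);
    if (!std::isfinite(mx))
      stop("non-finite emission likelihood at step %d", t + 1);
    for (int k = 0; k < L; ++k)
      lik[(size_t)k * Ttot + t] = std::exp(loglik(t, k) - mx);
  }

  IntegerVector z(Ttot);
  std::vector<double> msg;
  std::vector<double> prob(L);

  for (int r = 0; r < run_start.size(); ++r) {
    const int s = run_start[r];
    const int T = run_length[r];
    if (s < 0 || s + T > Ttot) stop("run indices out of range");
    msg.assign((size_t)T * L, 1.0);
    // backward: msg[t][k] proportional to p(y_{t+1..T} | z_t = k)
    for (int t = T - 2; t >= 0; --t) {
      double tot = 0.0;
      for (int k = 0; k < L; ++k) {
        double acc = 0.0;
        for (int j = 0; j < L; ++j)
          acc += Pi(k, j) * lik[(size_t)j * Ttot + s + t + 1] *
                 msg[(size_t)(t + 1) * L + j];
        msg[(size_t)t * L + k] = acc;
        tot += acc;
      }
      if (tot <= 0.0)
        stop("vanishing backward message at step %d of run %d", t + 1, r + 1);
      const double inv = 1.0 / tot;
      for (int k = 0; k < L; ++k) msg[(size_t)t * L + k] *= inv;
    }
    // forward sampling
    int prev = -1;
    for (int t = 0; t < T; ++t) {
      double tot = 0.0;
      for (int k = 0; k < L; ++k) {
        const double w = (t == 0 ? pi0[k] : Pi(prev, k)) *
                         lik[(size_t)k * Ttot + s + t] *
                         msg[(size_t)t * L + k];
        prob[k] = w;
        tot += w;
      }
      if (tot <= 0.0)
        stop("vanishing state posterior at step %d of run %d", t + 1, r + 1);
      const double target = u[s + t] * tot;
      double cum = 0.0;
      int pick = L - 1;
      for (int k = 0; k < L; ++k) {
        cum += prob[k];
        if (cum >= target) { pick = k; break; }
      }
      z[s + t] = pick + 1;
      prev = pick;
    }
  }
  return z;
}

// Per-step bivariate Gaussian emission log densities for every state.
// x: T x 2 displacements; mu: L x 2; sig: L x 3 (s11, s22, s12).
// [[Rcpp::export]]
NumericMatrix cpp_emission_loglik(const NumericMatrix& x,
                                  const NumericMatrix& mu,
                                  const NumericMatrix& sig) {
  const int T = x.nrow(), L = mu.nrow();
  if (x.ncol() != 2 || mu.ncol() != 2 || sig.ncol() != 3 || sig.nrow() != L)
    stop("cpp_emission_loglik: bad shapes");
  NumericMatrix out(T, L);
  const double l2pi = std::log(2.0 * M_PI);
  for (int k = 0; k < L; ++k) {
    const double a = sig(k, 0), d = sig(k, 1), b = sig(k, 2);
    const double det = a * d - b * b;
    if (det <= 0 || a <= 0 || d <= 0)
      stop("emission covariance for state %d is not positive definite", k + 1);
    const double ia = d / det, id = a / det, ib = -b / det;
    const double cst = -l2pi - 0.5 * std::log(det);
    const double m1 = mu(k, 0), m2 = mu(k, 1);
    for (int t = 0; t < T; ++t) {
      const double e1 = x(t, 0) - m1, e2 = x(t, 1) - m2;
      out(t, k) = cst - 0.5 * (ia * e1 * e1 + 2.0 * ib * e1 * e2 + id * e2 * e2);
    }
  }
  return out;
}
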