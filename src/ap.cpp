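#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Affinity-propagation message passing (responsibility/availability updates
// with damping).  Deterministic: no noise is added to S, so ties resolve by
// index order everywhere.  Convergence = a non-empty exemplar indicator
// vector unchanged for conv_iter consecutive sweeps.
//
// Matrices are held row-major (index k + n*i) so every inner loop over k is
// contiguous; the availability column sums are accumulated in a separate
// contiguous pass.
// [[Rcpp::export(name = ".ap_messages")]]
List ap_messages(NumericMatrix S, double damping, int max_iter, int conv_iter) {
  const int n = S.nrow();
  const double keep = damping, upd = 1.0 - damping;
  // Degenerate symmetric inputs make the noise-free messages oscillate, so a
  // vanishing relative jitter (~1e-16, the Frey-Dueck remedy) is folded into
  // S.  The jitter comes from a fixed linear congruential sequence, keeping
  // runs bit-reproducible.
  std::vector<double> St(static_cast<size_t>(n) * n);   // St[k + n*i] = S(i,k)
  uint32_t lcg = 123456789u;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < n; ++k) {
      lcg = lcg * 1103515245u + 12345u;
      const double u = static_cast<double>(lcg) / 4294967296.0 - 0.5;
      const double s = S(i, k);
      St[k + static_cast<size_t>(n) * i] = s + 2.220446e-16 * std::fabs(s) * u;
    }
  std::vector<double> R(static_cast<size_t>(n) * n, 0.0);
  std::vector<double> A(static_cast<size_t>(n) * n, 0.0);
  std::vector<double> tot(n), rdiag(n);
  std::vector<int> ex(n, -1);
  int stable = 0, iter = 0, churn = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // responsibilities: R(i,k) <- S(i,k) - max_{k' != k} {A(i,k') + S(i,k')}
    for (int i = 0; i < n; ++i) {
      const double *s = &St[static_cast<size_t>(n) * i];
      const double *a = &A[static_cast<size_t>(n) * i];
      double *r = &R[static_cast<size_t>(n) * i];
      double m1 = -INFINITY, m2 = -INFINITY;
      int k1 = -1;
      for (int k = 0; k < n; ++k) {
        const double v = a[k] + s[k];
        if (v > m1) { m2 = m1; m1 = v; k1 = k; }
        else if (v > m2) { m2 = v; }
      }
      for (int k = 0; k < n; ++k)
        r[k] = keep * r[k] + upd * (s[k] - (k == k1 ? m2 : m1));
    }
    // availabilities:
    //   A(i,k) <- min{0, R(k,k) + sum_{i' not in {i,k}} max(0, R(i',k))}
    //   A(k,k) <- sum_{i' != k} max(0, R(i',k))
    std::fill(tot.begin(), tot.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double *r = &R[static_cast<size_t>(n) * i];
      for (int k = 0; k < n; ++k) tot[k] += std::max(0.0, r[k]);
    }
    for (int k = 0; k < n; ++k) {
      rdiag[k] = R[k + static_cast<size_t>(n) * k];
      tot[k] -= std::max(0.0, rdiag[k]);   // exclude i' = k
    }
    for (int i = 0; i < n; ++i) {
      const double *r = &R[static_cast<size_t>(n) * i];
      double *a = &A[static_cast<size_t>(n) * i];
      for (int k = 0; k < n; ++k) {
        double v;
        if (i == k) {
          v = tot[k];
        } else {
          v = std::min(0.0, rdiag[k] + tot[k] - std::max(0.0, r[k]));
        }
        a[k] = keep * a[k] + upd * v;
      }
    }
    // exemplar indicator and convergence bookkeeping; an empty exemplar
    // set is never counted as stable (messages are still warming up)
    bool changed = false;
    int n_ex = 0;
    for (int k = 0; k < n; ++k) {
      const size_t d = k + static_cast<size_t>(n) * k;
      const int e = (R[d] + A[d]) > 0.0 ? 1 : 0;
      if (e != ex[k]) changed = true;
      ex[k] = e;
      n_ex += e;
    }
    if (!changed && n_ex > 0) {
      if (++stable >= conv_iter) { converged = true; break; }
      churn = 0;
    } else {
      stable = 1;  // current sweep counts as the first stable one
      // sustained sweep-to-sweep flipping = oscillation; give up early so
      // the caller can retry at higher damping
      if (changed && ++churn >= 60) break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  IntegerVector exemplars;
  NumericVector evidence(n);
  for (int k = 0; k < n; ++k) {
    const size_t d = k + static_cast<size_t>(n) * k;
    evidence[k] = R[d] + A[d];
    if (ex[k] == 1) exemplars.push_back(k + 1);  // 1-based for R
  }

  return List::create(_["exemplars"] = exemplars,
                      _["evidence"] = evidence,
                      _["n_iter"] = iter,
                      _["converged"] = converged);
}
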