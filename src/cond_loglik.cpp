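#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact conditional logistic log-likelihood, score and observed information,
// accumulated over strata. The denominator of each stratum's contribution is
// the elementary symmetric function of order d (number of cases) in the
// weights w_i = exp(eta_i), built by the recursion
//   f(j, r) = f(j-1, r) + w_j * f(j-1, r-1),
// with first and second derivatives with respect to beta propagated through
// the same recursion. eta is centered within each stratum (the conditional
// likelihood is invariant to a constant shift), and the f/h/q arrays are
// rescaled together if they grow large, so the computation is stable without
// working in log space.
//
// strat_start / strat_end are 1-based inclusive row ranges of each stratum;
// rows must be grouped by stratum.
// [[Rcpp::export]]
List cond_stats_cpp(NumericVector eta, NumericMatrix X, IntegerVector y,
                    IntegerVector strat_start, IntegerVector strat_end) {
  const int p = X.ncol();
  const int S = strat_start.size();
  double ll = 0.0;
  NumericVector score(p);
  NumericMatrix info(p, p);
  int informative = 0;

  std::vector<double> f, h, q;
  for (int s = 0; s < S; ++s) {
    const int a = strat_start[s] - 1;
    const int b = strat_end[s] - 1;
    const int n = b - a + 1;
    int d = 0;
    for (int i = a; i <= b; ++i) d += y[i];
    if (d == 0 || d == n) continue;  // non-informative: contributes nothing
    ++informative;

    double m = 0.0;
    for (int i = a; i <= b; ++i) m += eta[i];
    m /= n;

    f.assign(d + 1, 0.0);
    h.assign((size_t)(d + 1) * p, 0.0);
    q.assign((size_t)(d + 1) * p * p, 0.0);
    f[0] = 1.0;
    double log_scale = 0.0;

    for (int i = a; i <= b; ++i) {
      const double w = std::exp(eta[i] - m);
      const int rmax = std::min(d, i - a + 1);
      for (int r = rmax; r >= 1; --r) {
        double *qr = &q[(size_t)r * p * p];
        double *qr1 = &q[(size_t)(r - 1) * p * p];
        double *hr = &h[(size_t)r * p];
        double *hr1 = &h[(size_t)(r - 1) * p];
        const double f1 = f[r - 1];
        for (int j = 0; j < p; ++j) {
          const double xj = X(i, j);
          for (int k = 0; k <= j; ++k) {
            const double xk = X(i, k);
            qr[j * p + k] += w * (qr1[j * p + k] + xj * hr1[k] +
                                  xk * hr1[j] + xj * xk * f1);
          }
          hr[j] += w * (hr1[j] + xj * f1);
        }
        f[r] += w * f1;
      }
      if (f[std::min(d, i - a + 1)] > 1e250) {
        const double sc = 1e-250;
        for (int r = 0; r <= d; ++r) f[r] *= sc;
        for (size_t t = 0; t < h.size(); ++t) h[t] *= sc;
        for (size_t t = 0; t < q.size(); ++t) q[t] *= sc;
        log_scale += 250.0 * std::log(10.0);
      }
    }

    double num = 0.0;
    for (int i = a; i <= b; ++i)
      if (y[i]) {
        num += eta[i] - m;
        for (int j = 0; j < p; ++j) score[j] += X(i, j);
      }
    const double fd = f[d];
    ll += num - (std::log(fd) + log_scale);
    double *hd = &h[(size_t)d * p];
    double *qd = &q[(size_t)d * p * p];
    for (int j = 0; j < p; ++j) {
      const double ej = hd[j] / fd;  // conditional expectation of sum of x_j
      score[j] -= ej;
      for (int k = 0; k <= j; ++k) {
        const double cov = qd[j * p + k] / fd - ej * (hd[k] / fd);
        info(j, k) += cov;
      }
    }
  }
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) info(j, k) = info(k, j);

  return List::create(_["loglik"] = ll, _["score"] = score,
                      _["info"] = info, _["n_informative"] = informative);
}
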