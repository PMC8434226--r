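#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// log-domain global alignment kernel between two univariate sequences.
// Local kernel is Cuturi's infinitely divisible form
//   kappa(x, y) = k / (2 - k),  k = exp(-(x - y)^2 / (2 sigma^2)),
// summed over all monotone alignment paths by dynamic programming.

static inline double logsum3(double a, double b, double c) {
  double m = a;
  if (b > m) m = b;
  if (c > m) m = c;
  if (m == R_NegInf) return R_NegInf;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

static inline double local_logk(double x, double y, double sigma) {
  double d2 = (x - y) * (x - y);
  double lk = -d2 / (2.0 * sigma * sigma);
  // log(k / (2 - k)) = lk - log(2 - exp(lk)); exp(lk) <= 1 so safe
  return lk - std::log(2.0 - std::exp(lk));
}

// [[Rcpp::export(name = ".gak_log_cpp")]]
double gak_log_cpp(NumericVector x, NumericVector y, double sigma) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (sigma <= 0) stop("sigma must be positive");
  std::vector<double> prev(m + 1, R_NegInf), cur(m + 1, R_NegInf);
  prev[0] = 0.0;  // empty alignment
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      double lk = local_logk(x[i - 1], y[j - 1], sigma);
      cur[j] = lk + logsum3(prev[j], cur[j - 1], prev[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".gak_gram_cpp")]]
NumericMatrix gak_gram_cpp(List seqs, double sigma, bool normalize) {
  int n = seqs.size();
  std::vector<NumericVector> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = as<NumericVector>(seqs[i]);
  NumericVector diag_log(n);
  for (int i = 0; i < n; ++i) diag_log[i] = gak_log_cpp(xs[i], xs[i], sigma);
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = normalize ? 1.0 : std::exp(diag_log[i]);
    for (int j = i + 1; j < n; ++j) {
      double lk = gak_log_cpp(xs[i], xs[j], sigma);
      double v = normalize
        ? std::exp(lk - 0.5 * (diag_log[i] + diag_log[j]))
        : std::exp(lk);
      K(i, j) = v;
      K(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return K;
}

// minimum sliding-window Euclidean distance between a shapelet and a series
// [[Rcpp::export(name = ".min_dist_cpp")]]
double min_dist_cpp(NumericVector s, NumericVector x, bool normalize) {
  int L = s.size(), n = x.size();
  if (L > n) stop("shapelet longer than series");
  double best = R_PosInf;
  for (int p = 0; p + L <= n; ++p) {
    double acc = 0.0;
    for (int j = 0; j < L; ++j) {
      double d = x[p + j] - s[j];
      acc += d * d;
      if (acc >= best) break;  // early abandon
    }
    if (acc < best) best = acc;
  }
  if (normalize) best /= (double)L;
  return std::sqrt(best);
}
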