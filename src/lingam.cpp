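// DirectLiNGAM causal-ordering core.
//
// The ordering loop evaluates the maximum-entropy approximation of
// differential entropy over O(p^2) residual vectors per step; it is the
// hot path of the bootstrap ensemble and is therefore compiled, with the
// residual construction, standardization and entropy moments fused into a
// single pass. For sample-standardized columns with correlation rho the
// least-squares residual has mean 0 and sample SD sqrt(1 - rho^2) exactly,
// so no extra moment pass is needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double K1 = 79.047;
static const double K2 = 7.4129;
static const double GAM = 0.37457;
static const double LOG2 = 0.6931471805599453;

// Maximum-entropy approximation of differential entropy for a
// standardized variate with moments m1 = E log cosh u and
// m2 = E u exp(-u^2/2):
//   H(nu) - k1 (m1 - gamma)^2 - k2 m2^2,  H(nu) = (1 + log 2 pi)/2
static inline double entropy_from_moments(double m1, double m2) {
  const double hnu = 0.5 * (1.0 + std::log(2.0 * M_PI));
  return hnu - K1 * (m1 - GAM) * (m1 - GAM) - K2 * m2 * m2;
}

// log cosh u = |u| + log1p(exp(-2|u|)) - log 2, overflow-safe
static inline double log_cosh(double u) {
  const double a = std::fabs(u);
  return a + std::log1p(std::exp(-2.0 * a)) - LOG2;
}

// entropy of a standardized column
static double entropy_std(const double* x, uword n) {
  double m1 = 0.0, m2 = 0.0;
  for (uword i = 0; i < n; ++i) {
    const double u = x[i];
    m1 += log_cosh(u);
    m2 += u * std::exp(-0.5 * u * u);
  }
  return entropy_from_moments(m1 / n, m2 / n);
}

// entropy of the standardized residual (xb - rho * xa) / sqrt(1 - rho^2),
// both columns already standardized
static double entropy_residual(const double* xa, const double* xb,
                               double rho, uword n) {
  const double v = 1.0 - rho * rho;
  if (v < 1e-12) Rcpp::stop("collinear variable pair in ordering step");
  const double inv_s = 1.0 / std::sqrt(v);
  double m1 = 0.0, m2 = 0.0;
  for (uword i = 0; i < n; ++i) {
    const double u = (xb[i] - rho * xa[i]) * inv_s;
    m1 += log_cosh(u);
    m2 += u * std::exp(-0.5 * u * u);
  }
  return entropy_from_moments(m1 / n, m2 / n);
}

static vec standardize(const vec& x) {
  const double s = stddev(x);
  if (!(s > 0.0)) Rcpp::stop("zero-variance variable");
  return (x - mean(x)) / s;
}

// [[Rcpp::export]]
double cpp_pairwise_measure(const arma::vec& x, const arma::vec& y) {
  if (x.n_elem != y.n_elem || x.n_elem < 3)
    Rcpp::stop("x and y must have equal length >= 3");
  const uword n = x.n_elem;
  const vec xs = standardize(x);
  const vec ys = standardize(y);
  const double rho = dot(xs, ys) / (n - 1.0);
  // log-likelihood ratio of the model x -> y against y -> x
  return entropy_std(ys.memptr(), n)
       + entropy_residual(ys.memptr(), xs.memptr(), rho, n)
       - entropy_std(xs.memptr(), n)
       - entropy_residual(xs.memptr(), ys.memptr(), rho, n);
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_causal_order(const arma::mat& X) {
  const uword p = X.n_cols;
  const uword n = X.n_rows;
  const double n1 = static_cast<double>(n) - 1.0;
  if (n <= p) Rcpp::stop("need more rows than columns");

  mat W(n, p);
  for (uword j = 0; j < p; ++j) W.col(j) = standardize(X.col(j));

  std::vector<uword> remaining(p);
  for (uword j = 0; j < p; ++j) remaining[j] = j;
  std::vector<uword> order;
  order.reserve(p);

  while (remaining.size() > 1) {
    const uword k = remaining.size();
    vec H(k);
    for (uword a = 0; a < k; ++a)
      H(a) = entropy_std(W.colptr(remaining[a]), n);

    // antisymmetric direction measure M(a -> b): log-LR favoring a -> b
    mat M(k, k, fill::zeros);
    for (uword a = 0; a < k; ++a) {
      const double* xa = W.colptr(remaining[a]);
      for (uword b = a + 1; b < k; ++b) {
        const double* xb = W.colptr(remaining[b]);
        double rho = 0.0;
        for (uword i = 0; i < n; ++i) rho += xa[i] * xb[i];
        rho /= n1;
        const double m = H(b) + entropy_residual(xb, xa, rho, n)
                       - H(a) - entropy_residual(xa, xb, rho, n);
        M(a, b) = m;
        M(b, a) = -m;
      }
    }

    // exogeneity score: sum of squared negative parts; smallest wins,
    // ties broken by the lowest variable index
    uword best = 0;
    double best_t = datum::inf;
    for (uword a = 0; a < k; ++a) {
      double t = 0.0;
      for (uword b = 0; b < k; ++b) {
        if (b == a) continue;
        const double m = std::min(0.0, M(a, b));
        t += m * m;
      }
      if (t < best_t || (t == best_t && remaining[a] < remaining[best])) {
        best_t = t;
        best = a;
      }
    }

    const uword sel = remaining[best];
    order.push_back(sel);

    // regress the selected variable out of the rest, re-standardize
    const vec xk = W.col(sel);
    for (uword a = 0; a < k; ++a) {
      if (a == best) continue;
      const uword j = remaining[a];
      const double rho = dot(W.col(j), xk) / n1;
      const double v = 1.0 - rho * rho;
      if (v < 1e-12)
        Rcpp::stop("residual update leaves zero variance for a variable");
      W.col(j) = (W.col(j) - rho * xk) / std::sqrt(v);
    }
    remaining.erase(remaining.begin() + best);
  }
  order.push_back(remaining[0]);

  Rcpp::IntegerVector out(p);
  for (uword j = 0; j < p; ++j) out[j] = static_cast<int>(order[j]) + 1;
  return out;
}
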