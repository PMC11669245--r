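// Separable Gaussian / Gaussian-derivative filtering and Sobel gradients on
// 3D stacks stored as R arrays with dim (ny, nx, nz), i.e. [y, x, z] with y
// varying fastest. All boundaries use symmetric reflection (a b c | c b a).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// reflect index into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

static std::vector<double> gauss_kernel(double sigma, int order) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  const double s2 = sigma * sigma;
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * i * i / s2);
  if (order == 0) {
    double s = 0.0;
    for (double v : k) s += v;
    for (double& v : k) v /= s;
  } else if (order == 1) {
    // antisymmetric; normalized so the response to f(x) = x is exactly 1
    double s = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] *= i; s += (double)i * k[i + r]; }
    for (double& v : k) v /= s;
  } else {
    // second derivative; zero-sum (constants map to 0), response to x^2/2 is 1
    double s0 = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] *= (i * i / (s2 * s2) - 1.0 / s2);
      s0 += k[i + r];
    }
    const double n = 2.0 * r + 1.0;
    double s2m = 0.0;
    for (int i = -r; i <= r; ++i) { k[i + r] -= s0 / n; s2m += i * i * k[i + r]; }
    for (double& v : k) v *= 2.0 / s2m;
  }
  return k;
}

// correlate along one axis: out(x) = sum_i k[i] * in(x + i - r).
// Each line is gathered into a contiguous reflect-padded buffer so the inner
// product is branch-free and vectorizable.
static void filter_axis(const double* in, double* out,
                        int ny, int nx, int nz, int axis,
                        const std::vector<double>& k) {
  const int r = ((int)k.size() - 1) / 2;
  const int m = 2 * r + 1;
  const int n = (axis == 0) ? ny : (axis == 1) ? nx : nz;
  const int stride = (axis == 0) ? 1 : (axis == 1) ? ny : ny * nx;
  // iterate over all lines along `axis`
  const int n1 = (axis == 0) ? nx : ny;
  const int n2 = (axis == 2) ? nx : nz;
  const int s1 = (axis == 0) ? ny : 1;
  const int s2 = (axis == 2) ? ny : ny * nx;
  std::vector<double> buf(n + 2 * r);
  const double* kk = k.data();
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      const double* src = in + (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      double* dst = out + (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
      for (int i = 0; i < n; ++i) buf[r + i] = src[(R_xlen_t)i * stride];
      for (int i = 0; i < r; ++i) {
        buf[i] = buf[r + reflect_idx(i - r, n)];
        buf[n + r + i] = buf[r + reflect_idx(n + i, n)];
      }
      for (int i = 0; i < n; ++i) {
        const double* b0 = buf.data() + i;
        double acc = 0.0;
        for (int j = 0; j < m; ++j) acc += kk[j] * b0[j];
        dst[(R_xlen_t)i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector a, int ny, int nx, int nz,
                         NumericVector sigma, IntegerVector order) {
  NumericVector out = clone(a);
  NumericVector tmp(a.size());
  double* cur = REAL(out);
  double* buf = REAL(tmp);
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    const int o = order[axis];
    if (s <= 0.0 && o == 0) continue;  // identity pass
    if (s <= 0.0) stop("derivative order > 0 requires sigma > 0");
    std::vector<double> k = gauss_kernel(s, o);
    filter_axis(cur, buf, ny, nx, nz, axis, k);
    std::swap(cur, buf);
  }
  if (cur == REAL(out)) return out;
  return tmp;
}

// Sobel gradient magnitude in index space: per-axis derivative [-1,0,1]/2
// with [1,2,1]/4 smoothing in the two orthogonal axes.
// [[Rcpp::export]]
NumericVector cpp_sobel3(NumericVector a, int ny, int nx, int nz) {
  const std::vector<double> d = {-0.5, 0.0, 0.5};
  const std::vector<double> s = {0.25, 0.5, 0.25};
  NumericVector out(a.size());
  NumericVector t1(a.size()), t2(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    const double* src = REAL(a);
    double* b1 = REAL(t1);
    double* b2 = REAL(t2);
    filter_axis(src, b1, ny, nx, nz, axis, d);
    for (int other = 0; other < 3; ++other) {
      if (other == axis) continue;
      filter_axis(b1, b2, ny, nx, nz, other, s);
      std::swap(b1, b2);
    }
    double* o = REAL(out);
    for (R_xlen_t i = 0; i < a.size(); ++i) o[i] += b1[i] * b1[i];
  }
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < a.size(); ++i) o[i] = std::sqrt(o[i]);
  return out;
}

// Eigenvalues (descending) of symmetric 3x3 matrices given as 6 planes
// (xx, xy, xz, yy, yz, zz); returns 3 planes.
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigenvalues(NumericMatrix m6) {
  const R_xlen_t n = m6.nrow();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = m6(i, 0), b = m6(i, 3), c = m6(i, 5);
    double d = m6(i, 1), e = m6(i, 4), f = m6(i, 2);
    // analytic eigenvalues of [[a d f],[d b e],[f e c]]
    double p1 = d * d + f * f + e * e;
    double q = (a + b + c) / 3.0;
    double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                2.0 * p1;
    double p = std::sqrt(std::max(p2 / 6.0, 0.0));
    double e1, e2, e3;
    if (p < 1e-300) {
      e1 = e2 = e3 = q;
    } else {
      double ia = (a - q) / p, ib = (b - q) / p, ic = (c - q) / p;
      double id = d / p, ie = e / p, iff = f / p;
      double detB = ia * (ib * ic - ie * ie) - id * (id * ic - ie * iff) +
                    iff * (id * ie - ib * iff);
      double r = detB / 2.0;
      r = std::min(1.0, std::max(-1.0, r));
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}
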