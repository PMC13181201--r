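// Discrete radon transform (ray-driven line integrals with bilinear
// sampling) and the interpolating back-projector plus its adjoint.
//
// Image convention (shared with the R side): n x n matrix, pixel centres on
// a uniform grid over [-1,1]^2, row index increasing downward, so for
// 0-based indices (i, j):
//   x =  (j - (n-1)/2) * px,   y = -(i - (n-1)/2) * px.
// A ray with angle theta and detector offset s is
//   p(r) = s*(cos t, sin t) + r*(-sin t, cos t),  t = theta.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double bilin(const mat& img, double x, double y, double px,
                           double c0) {
  // c0 = (n-1)/2; returns 0 outside the grid
  const int n = img.n_rows;
  const double colf = x / px + c0;
  const double rowf = -y / px + c0;
  const int j0 = (int)std::floor(colf);
  const int i0 = (int)std::floor(rowf);
  if (j0 < -1 || j0 > n - 1 || i0 < -1 || i0 > n - 1) return 0.0;
  const double wx = colf - j0, wy = rowf - i0;
  double v = 0.0;
  if (i0 >= 0 && j0 >= 0)          v += (1 - wy) * (1 - wx) * img(i0, j0);
  if (i0 >= 0 && j0 + 1 <= n - 1)  v += (1 - wy) * wx * img(i0, j0 + 1);
  if (i0 + 1 <= n - 1 && j0 >= 0)  v += wy * (1 - wx) * img(i0 + 1, j0);
  if (i0 + 1 <= n - 1 && j0 + 1 <= n - 1) v += wy * wx * img(i0 + 1, j0 + 1);
  return v;
}

// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, const arma::vec& angles, int m1,
                    double s0, double ds, double px, double step,
                    double rmax) {
  const int m2 = angles.n_elem;
  const double c0 = (img.n_rows - 1) / 2.0;
  mat sino(m1, m2, fill::zeros);
  const int nr = (int)std::ceil(2.0 * rmax / step);
  for (int a = 0; a < m2; ++a) {
    const double ct = std::cos(angles(a)), st = std::sin(angles(a));
    for (int i = 0; i < m1; ++i) {
      const double s = s0 + i * ds;
      double acc = 0.0;
      double r = -rmax;
      for (int k = 0; k <= nr; ++k, r += step) {
        const double x = s * ct - r * st;
        const double y = s * st + r * ct;
        acc += bilin(img, x, y, px, c0);
      }
      sino(i, a) = acc * step;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& fs, const arma::vec& angles,
                          double s0, double ds, int n, double px,
                          double scale) {
  const int m1 = fs.n_rows, m2 = fs.n_cols;
  const double c0 = (n - 1) / 2.0;
  mat img(n, n, fill::zeros);
  for (int a = 0; a < m2; ++a) {
    const double ct = std::cos(angles(a)), st = std::sin(angles(a));
    for (int j = 0; j < n; ++j) {
      const double x = (j - c0) * px;
      for (int i = 0; i < n; ++i) {
        const double y = -(i - c0) * px;
        const double u = (x * ct + y * st - s0) / ds;
        const int k = (int)std::floor(u);
        if (k < -1 || k > m1 - 1) continue;
        const double w = u - k;
        double v = 0.0;
        if (k >= 0) v += (1 - w) * fs(k, a);
        if (k + 1 <= m1 - 1) v += w * fs(k + 1, a);
        img(i, j) += v;
      }
    }
  }
  return img * scale;
}

// adjoint of cpp_backproject (same scale factor applied)
// [[Rcpp::export]]
arma::mat cpp_backproject_adj(const arma::mat& dimg, const arma::vec& angles,
                              double s0, double ds, int m1, double px,
                              double scale) {
  const int n = dimg.n_rows, m2 = angles.n_elem;
  const double c0 = (n - 1) / 2.0;
  mat dfs(m1, m2, fill::zeros);
  for (int a = 0; a < m2; ++a) {
    const double ct = std::cos(angles(a)), st = std::sin(angles(a));
    for (int j = 0; j < n; ++j) {
      const double x = (j - c0) * px;
      for (int i = 0; i < n; ++i) {
        const double y = -(i - c0) * px;
        const double u = (x * ct + y * st - s0) / ds;
        const int k = (int)std::floor(u);
        if (k < -1 || k > m1 - 1) continue;
        const double w = u - k;
        const double g = dimg(i, j);
        if (k >= 0) dfs(k, a) += (1 - w) * g;
        if (k + 1 <= m1 - 1) dfs(k + 1, a) += w * g;
      }
    }
  }
  return dfs * scale;
}
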