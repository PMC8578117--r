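// Computational kernels for free-form-deformation warping and per-pixel
// kinetic model fitting. Images are passed as column-major arrays with an
// explicit dim vector (x fastest); coordinates are 0-based voxel-centre
// positions in pixel units. Deformation maps corrected-frame coordinates to
// source-frame coordinates (backward warping); out-of-bounds source
// coordinates are clamped to the image edge.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Locate coordinate u (pixel units) on a lattice of m nodes spaced h apart
// starting at 0: cell index i0 in [0, m-2] and fraction f in [0, 1].
static inline void cell_frac(double u, int m, double h, int &i0, double &f) {
  double v = u / h;
  if (v <= 0.0) { i0 = 0; f = 0.0; return; }
  if (v >= (double)(m - 1)) { i0 = m - 2; f = 1.0; return; }
  i0 = (int)std::floor(v);
  if (i0 > m - 2) i0 = m - 2;
  f = v - (double)i0;
}

// Tent-kernel interpolation of a d-dimensional image (d = 2 or 3) at point
// p, with the exact derivative of the interpolant with respect to each
// coordinate (zero where the coordinate is clamped outside the image).
static inline double sample_image(const double *img, const int *n, int d,
                                  const double *p, double *grad) {
  int i0[3] = {0, 0, 0};
  double f[3] = {0.0, 0.0, 0.0};
  bool clamped[3] = {false, false, false};
  for (int a = 0; a < d; ++a) {
    double v = p[a];
    if (v <= 0.0) {
      i0[a] = 0; f[a] = 0.0; clamped[a] = (v < 0.0);
    } else if (v >= (double)(n[a] - 1)) {
      i0[a] = n[a] - 2; f[a] = 1.0; clamped[a] = (v > (double)(n[a] - 1));
    } else {
      i0[a] = (int)std::floor(v); f[a] = v - (double)i0[a];
    }
  }
  int stride[3] = {1, n[0], n[0] * n[1]};
  double val = 0.0;
  if (grad) for (int a = 0; a < d; ++a) grad[a] = 0.0;
  int ncorner = 1 << d;
  for (int c = 0; c < ncorner; ++c) {
    double w = 1.0;
    int idx = 0;
    for (int a = 0; a < d; ++a) {
      int bit = (c >> a) & 1;
      w *= bit ? f[a] : 1.0 - f[a];
      idx += (i0[a] + bit) * stride[a];
    }
    double s = img[idx];
    val += w * s;
    if (grad) {
      for (int a = 0; a < d; ++a) {
        if (clamped[a]) continue;
        double dw = ((c >> a) & 1) ? 1.0 : -1.0;
        for (int b = 0; b < d; ++b) {
          if (b == a) continue;
          int bit = (c >> b) & 1;
          dw *= bit ? f[b] : 1.0 - f[b];
        }
        grad[a] += dw * s;
      }
    }
  }
  return val;
}

// Displacement at voxel-centre x from a control-point lattice (tent kernel,
// partition of unity inside the hull).
static inline void ctrl_disp_at(const double *dsp, const int *m, int d,
                                const double *h, const double *x,
                                double *out) {
  int i0[3] = {0, 0, 0};
  double f[3] = {0.0, 0.0, 0.0};
  for (int a = 0; a < d; ++a) cell_frac(x[a], m[a], h[a], i0[a], f[a]);
  int stride[3] = {1, m[0], m[0] * m[1]};
  int nctrl = m[0] * m[1] * (d == 3 ? m[2] : 1);
  for (int a = 0; a < d; ++a) out[a] = 0.0;
  int ncorner = 1 << d;
  for (int c = 0; c < ncorner; ++c) {
    double w = 1.0;
    int idx = 0;
    for (int a = 0; a < d; ++a) {
      int bit = (c >> a) & 1;
      w *= bit ? f[a] : 1.0 - f[a];
      idx += (i0[a] + bit) * stride[a];
    }
    for (int a = 0; a < d; ++a) out[a] += w * dsp[idx + a * nctrl];
  }
}

// Dense displacement field (one row per voxel, one column per axis) from a
// control grid. img_dim gives the spatial image dimensions.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_dense(NumericMatrix ctrl_disp, IntegerVector ctrl_dims,
                            NumericVector spacing, IntegerVector img_dim) {
  int d = img_dim.size();
  int n[3] = {img_dim[0], d > 1 ? img_dim[1] : 1, d > 2 ? img_dim[2] : 1};
  int m[3] = {ctrl_dims[0], d > 1 ? ctrl_dims[1] : 1,
              d > 2 ? ctrl_dims[2] : 1};
  double h[3] = {spacing[0], d > 1 ? spacing[1] : 1.0,
                 d > 2 ? spacing[2] : 1.0};
  int nvox = n[0] * n[1] * n[2];
  NumericMatrix out(nvox, d);
  const double *dsp = ctrl_disp.begin();
  int v = 0;
  double x[3], u[3];
  for (int iz = 0; iz < n[2]; ++iz)
    for (int iy = 0; iy < n[1]; ++iy)
      for (int ix = 0; ix < n[0]; ++ix, ++v) {
        x[0] = ix; x[1] = iy; x[2] = iz;
        ctrl_disp_at(dsp, m, d, h, x, u);
        for (int a = 0; a < d; ++a) out(v, a) = u[a];
      }
  return out;
}

// Backward warp of an image by a dense displacement field, optionally with
// the exact interpolant gradient with respect to the sampling coordinate.
// [[Rcpp::export]]
List cpp_warp_dense(NumericVector image, NumericMatrix disp,
                    IntegerVector img_dim, bool want_grad) {
  int d = img_dim.size();
  int n[3] = {img_dim[0], d > 1 ? img_dim[1] : 1, d > 2 ? img_dim[2] : 1};
  int nvox = n[0] * n[1] * n[2];
  NumericVector val(nvox);
  NumericMatrix grd(want_grad ? nvox : 1, want_grad ? d : 1);
  const double *img = image.begin();
  int v = 0;
  double p[3], g[3];
  for (int iz = 0; iz < n[2]; ++iz)
    for (int iy = 0; iy < n[1]; ++iy)
      for (int ix = 0; ix < n[0]; ++ix, ++v) {
        p[0] = ix + disp(v, 0);
        if (d > 1) p[1] = iy + disp(v, 1);
        if (d > 2) p[2] = iz + disp(v, 2);
        val[v] = sample_image(img, n, d, p, want_grad ? g : (double *)0);
        if (want_grad) for (int a = 0; a < d; ++a) grd(v, a) = g[a];
      }
  val.attr("dim") = img_dim;
  if (want_grad) return List::create(_["value"] = val, _["grad"] = grd);
  return List::create(_["value"] = val);
}

// Fused FFD warp: interpolate control-point displacements and sample the
// image in one pass. Returns the warped frame, and optionally the warped
// exact image gradient and the per-voxel cost contribution against a target.
// [[Rcpp::export]]
List cpp_warp_ffd(NumericVector image, NumericMatrix ctrl_disp,
                  IntegerVector ctrl_dims, NumericVector spacing,
                  IntegerVector img_dim, bool want_grad) {
  int d = img_dim.size();
  int n[3] = {img_dim[0], d > 1 ? img_dim[1] : 1, d > 2 ? img_dim[2] : 1};
  int m[3] = {ctrl_dims[0], d > 1 ? ctrl_dims[1] : 1,
              d > 2 ? ctrl_dims[2] : 1};
  double h[3] = {spacing[0], d > 1 ? spacing[1] : 1.0,
                 d > 2 ? spacing[2] : 1.0};
  int nvox = n[0] * n[1] * n[2];
  NumericVector val(nvox);
  NumericMatrix grd(want_grad ? nvox : 1, want_grad ? d : 1);
  const double *img = image.begin();
  const double *dsp = ctrl_disp.begin();
  int v = 0;
  double x[3], u[3], p[3], g[3];
  for (int iz = 0; iz < n[2]; ++iz)
    for (int iy = 0; iy < n[1]; ++iy)
      for (int ix = 0; ix < n[0]; ++ix, ++v) {
        x[0] = ix; x[1] = iy; x[2] = iz;
        ctrl_disp_at(dsp, m, d, h, x, u);
        for (int a = 0; a < d; ++a) p[a] = x[a] + u[a];
        val[v] = sample_image(img, n, d, p, want_grad ? g : (double *)0);
        if (want_grad) for (int a = 0; a < d; ++a) grd(v, a) = g[a];
      }
  val.attr("dim") = img_dim;
  if (want_grad) return List::create(_["value"] = val, _["grad"] = grd);
  return List::create(_["value"] = val);
}

// Analytical cost gradient over control points for one frame:
// G_j = sum over voxels in the tent support of W_j(x) * resid(x) * grad(x,.)
// where grad is the warped exact image gradient.
// [[Rcpp::export]]
NumericMatrix cpp_grad_ctrl(NumericVector resid, NumericMatrix grad,
                            IntegerVector ctrl_dims, NumericVector spacing,
                            IntegerVector img_dim) {
  int d = img_dim.size();
  int n[3] = {img_dim[0], d > 1 ? img_dim[1] : 1, d > 2 ? img_dim[2] : 1};
  int m[3] = {ctrl_dims[0], d > 1 ? ctrl_dims[1] : 1,
              d > 2 ? ctrl_dims[2] : 1};
  double h[3] = {spacing[0], d > 1 ? spacing[1] : 1.0,
                 d > 2 ? spacing[2] : 1.0};
  int stride[3] = {1, m[0], m[0] * m[1]};
  int nctrl = m[0] * m[1] * (d == 3 ? m[2] : 1);
  NumericMatrix G(nctrl, d);
  int v = 0;
  int i0[3] = {0, 0, 0};
  double f[3] = {0.0, 0.0, 0.0};
  double x[3];
  int ncorner = 1 << d;
  for (int iz = 0; iz < n[2]; ++iz)
    for (int iy = 0; iy < n[1]; ++iy)
      for (int ix = 0; ix < n[0]; ++ix, ++v) {
        double r = resid[v];
        if (r == 0.0) continue;
        x[0] = ix; x[1] = iy; x[2] = iz;
        for (int a = 0; a < d; ++a) cell_frac(x[a], m[a], h[a], i0[a], f[a]);
        for (int c = 0; c < ncorner; ++c) {
          double w = 1.0;
          int idx = 0;
          for (int a = 0; a < d; ++a) {
            int bit = (c >> a) & 1;
            w *= bit ? f[a] : 1.0 - f[a];
            idx += (i0[a] + bit) * stride[a];
          }
          if (w == 0.0) continue;
          for (int a = 0; a < d; ++a) G(idx, a) += w * r * grad(v, a);
        }
      }
  return G;
}

// Per-pixel ordinary least squares fit of the linearised two-compartment
// filtration model: (S - S0) regressed on the single and double cumulative
// trapezoid integrals of (S - S0) and of the arterial input function.
// Rank-deficient pixels (e.g. flat signal) get zero coefficients and a
// constant fitted curve at S0, flagged in `ok`.
// [[Rcpp::export]]
List cpp_fit2cfm(const arma::mat &Y, int n0, double dt, const arma::vec &ca1,
                 const arma::vec &ca2) {
  int T = Y.n_rows, P = Y.n_cols;
  arma::mat coef(4, P, arma::fill::zeros);
  arma::mat fitted(T, P);
  arma::vec s0(P);
  LogicalVector ok(P);
  arma::mat X(T, 4);
  X.col(2) = ca1;
  X.col(3) = ca2;
  arma::vec y(T), y1(T), y2(T), c;
  for (int p = 0; p < P; ++p) {
    double m = arma::mean(Y.col(p).head(n0));
    s0[p] = m;
    y = Y.col(p) - m;
    y1[0] = 0.0; y2[0] = 0.0;
    for (int t = 1; t < T; ++t) {
      y1[t] = y1[t - 1] + 0.5 * dt * (y[t] + y[t - 1]);
      y2[t] = y2[t - 1] + 0.5 * dt * (y1[t] + y1[t - 1]);
    }
    X.col(0) = y1;
    X.col(1) = y2;
    // QR least squares on X itself: the normal equations are too
    // ill-conditioned because the double integrals grow like t^2
    bool good = arma::solve(c, X, y, arma::solve_opts::no_approx);
    good = good && c.is_finite();
    if (good) {
      coef.col(p) = c;
      fitted.col(p) = m + X * c;
      ok[p] = true;
    } else {
      fitted.col(p).fill(m);
      ok[p] = false;
    }
  }
  return List::create(_["coef"] = coef, _["s0"] = s0, _["fitted"] = fitted,
                      _["ok"] = ok);
}

// Per-pixel modified Tofts fit over a fixed grid of efflux rates kep:
// C = vp * ca + Ktrans * (exp(-kep t) convolved with ca). For each kep the
// (vp, Ktrans) pair is the exact non-negative least squares solution of the
// two-regressor problem; the grid point with the smallest residual wins.
// B holds one convolved exponential basis per column.
// [[Rcpp::export]]
List cpp_fit_tofts(const arma::mat &Y, int n0, const arma::vec &ca,
                   const arma::mat &B, const arma::vec &kep) {
  int T = Y.n_rows, P = Y.n_cols, K = B.n_cols;
  arma::mat coef(3, P, arma::fill::zeros);
  arma::mat fitted(T, P);
  LogicalVector ok(P);
  arma::vec s0(P);
  double caca = arma::dot(ca, ca);
  arma::vec bb(K), cab(K);
  for (int k = 0; k < K; ++k) {
    bb[k] = arma::dot(B.col(k), B.col(k));
    cab[k] = arma::dot(ca, B.col(k));
  }
  arma::vec y(T);
  for (int p = 0; p < P; ++p) {
    double m = arma::mean(Y.col(p).head(n0));
    s0[p] = m;
    y = Y.col(p) - m;
    double yy = arma::dot(y, y);
    double yca = arma::dot(y, ca);
    double best_rss = yy;  // vp = Ktrans = 0 fallback
    double best_vp = 0.0, best_kt = 0.0, best_kep = kep[0];
    bool found = false;
    for (int k = 0; k < K; ++k) {
      double yb = arma::dot(y, B.col(k));
      double det = caca * bb[k] - cab[k] * cab[k];
      double vp, kt;
      if (det > 1e-12 * caca * bb[k]) {
        vp = (bb[k] * yca - cab[k] * yb) / det;
        kt = (caca * yb - cab[k] * yca) / det;
      } else {
        vp = -1.0; kt = -1.0;  // force boundary handling
      }
      if (vp < 0.0 || kt < 0.0) {
        // exact NNLS for two regressors: best feasible point is on an axis
        double vp1 = caca > 0 ? std::max(0.0, yca / caca) : 0.0;
        double rss1 = yy - 2 * vp1 * yca + vp1 * vp1 * caca;
        double kt2 = bb[k] > 0 ? std::max(0.0, yb / bb[k]) : 0.0;
        double rss2 = yy - 2 * kt2 * yb + kt2 * kt2 * bb[k];
        if (rss1 <= rss2) { vp = vp1; kt = 0.0; }
        else { vp = 0.0; kt = kt2; }
      }
      double rss = yy - 2 * vp * yca - 2 * kt * arma::dot(y, B.col(k)) +
                   vp * vp * caca + 2 * vp * kt * cab[k] + kt * kt * bb[k];
      if (rss < best_rss - 1e-15 * std::max(1.0, yy)) {
        best_rss = rss; best_vp = vp; best_kt = kt; best_kep = kep[k];
        found = true;
      }
    }
    coef(0, p) = best_vp;
    coef(1, p) = best_kt;
    coef(2, p) = best_kep;
    ok[p] = found;
    if (found) {
      int kbest = 0;
      for (int k = 0; k < K; ++k) if (kep[k] == best_kep) { kbest = k; break; }
      fitted.col(p) = m + best_vp * ca + best_kt * B.col(kbest);
    } else {
      fitted.col(p).fill(m);
    }
  }
  return List::create(_["coef"] = coef, _["s0"] = s0, _["fitted"] = fitted,
                      _["ok"] = ok);
}
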