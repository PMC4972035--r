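#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Separable correlation with replicate (clamp) boundary handling.
// kx runs along the first array dimension (detector x), ky along the second.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(const NumericMatrix& img,
                           const NumericVector& kx,
                           const NumericVector& ky) {
  const int nx = img.nrow(), ny = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nx, ny), out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int k = -rx; k <= rx; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= nx) ii = nx - 1;
        s += kx[k + rx] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int k = -ry; k <= ry; ++k) {
        int jj = j + k;
        if (jj < 0) jj = 0; else if (jj >= ny) jj = ny - 1;
        s += ky[k + ry] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}

// Analytic bead footprints: each bead adds its projected-sphere chord-length
// profile 2*density*sqrt(r^2 - rho^2) around its projected centre.
// pos2d holds projected centres in 0-based pixel coordinates.
// [[Rcpp::export]]
NumericMatrix splat_beads_cpp(int nx, int ny,
                              const NumericMatrix& pos2d,
                              const NumericVector& radius_px,
                              const NumericVector& density) {
  NumericMatrix img(nx, ny);
  const int nb = pos2d.nrow();
  for (int b = 0; b < nb; ++b) {
    const double cx = pos2d(b, 0), cy = pos2d(b, 1);
    const double r = radius_px[b], d = density[b];
    const int i0 = std::max(0, (int)std::floor(cx - r) - 1);
    const int i1 = std::min(nx - 1, (int)std::ceil(cx + r) + 1);
    const int j0 = std::max(0, (int)std::floor(cy - r) - 1);
    const int j1 = std::min(ny - 1, (int)std::ceil(cy + r) + 1);
    // 4x4 subpixel quadrature: the chord profile has a sqrt edge
    // singularity, and plain pixel-centre sampling leaves ~0.5 % mass
    // fluctuation with subpixel centre position.
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double acc = 0.0;
        for (int sy = 0; sy < 4; ++sy)
          for (int sx = 0; sx < 4; ++sx) {
            const double dx = i - 0.375 + 0.25 * sx - cx;
            const double dy = j - 0.375 + 0.25 * sy - cy;
            const double rho2 = dx * dx + dy * dy;
            if (rho2 < r * r) acc += std::sqrt(r * r - rho2);
          }
        if (acc > 0.0) img(i, j) += 2.0 * d * acc / 16.0;
      }
  }
  return img;
}

// Spherical-shell footprints: chord through the outer sphere minus the chord
// through the inner sphere.
// [[Rcpp::export]]
NumericMatrix splat_shells_cpp(int nx, int ny,
                               const NumericMatrix& pos2d,
                               const NumericVector& r_in_px,
                               const NumericVector& r_out_px,
                               const NumericVector& density) {
  NumericMatrix img(nx, ny);
  const int ns = pos2d.nrow();
  for (int s = 0; s < ns; ++s) {
    const double cx = pos2d(s, 0), cy = pos2d(s, 1);
    const double ri = r_in_px[s], ro = r_out_px[s], d = density[s];
    const int i0 = std::max(0, (int)std::floor(cx - ro) - 1);
    const int i1 = std::min(nx - 1, (int)std::ceil(cx + ro) + 1);
    const int j0 = std::max(0, (int)std::floor(cy - ro) - 1);
    const int j1 = std::min(ny - 1, (int)std::ceil(cy + ro) + 1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double acc = 0.0;
        for (int sy = 0; sy < 4; ++sy)
          for (int sx = 0; sx < 4; ++sx) {
            const double dx = i - 0.375 + 0.25 * sx - cx;
            const double dy = j - 0.375 + 0.25 * sy - cy;
            const double rho2 = dx * dx + dy * dy;
            if (rho2 < ro * ro) acc += std::sqrt(ro * ro - rho2);
            if (rho2 < ri * ri) acc -= std::sqrt(ri * ri - rho2);
          }
        if (acc != 0.0) img(i, j) += 2.0 * d * acc / 16.0;
      }
  }
  return img;
}

static inline void eval_map(const NumericMatrix& coef, const IntegerMatrix& expo,
                            double X, double Y, double Z,
                            double& u, double& v) {
  u = 0.0; v = 0.0;
  const int m = expo.nrow();
  for (int k = 0; k < m; ++k) {
    double mono = 1.0;
    for (int e = 0; e < expo(k, 0); ++e) mono *= X;
    for (int e = 0; e < expo(k, 1); ++e) mono *= Y;
    for (int e = 0; e < expo(k, 2); ++e) mono *= Z;
    u += coef(0, k) * mono;
    v += coef(1, k) * mono;
  }
}

// Voxel-driven forward projector: every voxel is projected through the map
// and its density, scaled by the per-voxel beam path length, is splatted into
// the image with bilinear weights.  proj_back_cpp is the exact transpose
// (identical weights and inclusion tests), so <Ax, y> == <x, A^T y> to
// machine precision.
// [[Rcpp::export]]
NumericMatrix proj_fwd_cpp(const NumericVector& vol, const IntegerVector& dim,
                           const NumericVector& origin, double voxel_size,
                           const NumericMatrix& coef, const IntegerMatrix& expo,
                           int nxi, int nyi, double path_len) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix img(nxi, nyi);
  int idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double Z = origin[2] + k * voxel_size;
    for (int j = 0; j < ny; ++j) {
      const double Y = origin[1] + j * voxel_size;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double val = vol[idx];
        if (val == 0.0) continue;
        const double X = origin[0] + i * voxel_size;
        double u, v;
        eval_map(coef, expo, X, Y, Z, u, v);
        const int iu = (int)std::floor(u), iv = (int)std::floor(v);
        const double fu = u - iu, fv = v - iv;
        const double w = val * path_len;
        if (iu >= 0 && iu < nxi) {
          if (iv >= 0 && iv < nyi)         img(iu, iv)         += w * (1 - fu) * (1 - fv);
          if (iv + 1 >= 0 && iv + 1 < nyi) img(iu, iv + 1)     += w * (1 - fu) * fv;
        }
        if (iu + 1 >= 0 && iu + 1 < nxi) {
          if (iv >= 0 && iv < nyi)         img(iu + 1, iv)     += w * fu * (1 - fv);
          if (iv + 1 >= 0 && iv + 1 < nyi) img(iu + 1, iv + 1) += w * fu * fv;
        }
      }
    }
  }
  return img;
}

// Transpose of proj_fwd_cpp: gathers bilinear samples of the image at each
// voxel's projection.  Accumulates into `vol` in place (passed from R as a
// fresh copy); `cover` counts micrographs whose footprint fully contains the
// voxel's projection.
// [[Rcpp::export]]
List proj_back_cpp(const NumericMatrix& img, const IntegerVector& dim,
                   const NumericVector& origin, double voxel_size,
                   const NumericMatrix& coef, const IntegerMatrix& expo,
                   double path_len, NumericVector vol, IntegerVector cover) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nxi = img.nrow(), nyi = img.ncol();
  int idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double Z = origin[2] + k * voxel_size;
    for (int j = 0; j < ny; ++j) {
      const double Y = origin[1] + j * voxel_size;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double X = origin[0] + i * voxel_size;
        double u, v;
        eval_map(coef, expo, X, Y, Z, u, v);
        const int iu = (int)std::floor(u), iv = (int)std::floor(v);
        const double fu = u - iu, fv = v - iv;
        double s = 0.0, wsum = 0.0;
        if (iu >= 0 && iu < nxi) {
          if (iv >= 0 && iv < nyi)         { s += img(iu, iv) * (1 - fu) * (1 - fv);     wsum += (1 - fu) * (1 - fv); }
          if (iv + 1 >= 0 && iv + 1 < nyi) { s += img(iu, iv + 1) * (1 - fu) * fv;       wsum += (1 - fu) * fv; }
        }
        if (iu + 1 >= 0 && iu + 1 < nxi) {
          if (iv >= 0 && iv < nyi)         { s += img(iu + 1, iv) * fu * (1 - fv);       wsum += fu * (1 - fv); }
          if (iv + 1 >= 0 && iv + 1 < nyi) { s += img(iu + 1, iv + 1) * fu * fv;         wsum += fu * fv; }
        }
        vol[idx] += path_len * s;
        if (wsum > 0.999999) cover[idx] += 1;
      }
    }
  }
  return List::create(_["vol"] = vol, _["cover"] = cover);
}

// Monte-Carlo missing-fraction counter: counts sampled Fourier points missed
// by every one of the n tilt wedges.
// [[Rcpp::export]]
int mc_missing_count_cpp(const NumericVector& kx, const NumericVector& ky,
                         const NumericVector& kz, const NumericVector& phi,
                         double tan_theta_max) {
  const int N = kx.size(), n = phi.size();
  int miss = 0;
  for (int i = 0; i < N; ++i) {
    double g = 0.0;
    for (int j = 0; j < n; ++j) {
      const double c = std::fabs(kx[i] * std::cos(phi[j]) + ky[i] * std::sin(phi[j]));
      if (c > g) g = c;
    }
    if (std::fabs(kz[i]) > tan_theta_max * g) ++miss;
  }
  return miss;
}
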