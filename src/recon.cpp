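#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Joseph-style interpolating line integrals for a parallel-beam geometry.
//
// Conventions (used package-wide): image is N x N with img(ix, iy) at
// x = (ix - N/2)*h, y = (iy - N/2)*h (0-based ix/iy, isocenter at index N/2);
// a projection at angle theta collects line integrals over
// x*cos(theta) + y*sin(theta) = t, with detector offsets t = (d - ndet/2)*dd.
// The integral steps one pixel at a time along the dominant axis of the ray
// and linearly interpolates along the other axis (Joseph's method).
// [[Rcpp::export]]
NumericMatrix cpp_project_parallel(NumericMatrix img, double h,
                                   NumericVector angles, int ndet, double dd) {
  const int N = img.nrow();
  const int nv = angles.size();
  NumericMatrix out(nv, ndet);
  const double half = 0.5 * N * h;
  const double rmax = half * M_SQRT2;  // rays beyond the image diagonal are zero

  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]);
    const double s = std::sin(angles[v]);
    for (int d = 0; d < ndet; ++d) {
      const double t = (d - ndet / 2) * dd;
      if (std::fabs(t) > rmax) continue;
      double acc = 0.0;
      if (std::fabs(s) >= std::fabs(c)) {
        // step across columns ix, interpolate in iy
        const double step = h / std::fabs(s);
        for (int ix = 0; ix < N; ++ix) {
          const double x = (ix - N / 2) * h;
          const double y = (t - x * c) / s;
          const double fy = y / h + N / 2;
          if (fy < 0.0 || fy > N - 1) continue;
          const int iy = (int)fy;
          const double w = fy - iy;
          const double lo = img(ix, iy);
          const double hi = (iy + 1 < N) ? img(ix, iy + 1) : 0.0;
          acc += (1.0 - w) * lo + w * hi;
        }
        out(v, d) = acc * step;
      } else {
        const double step = h / std::fabs(c);
        for (int iy = 0; iy < N; ++iy) {
          const double y = (iy - N / 2) * h;
          const double x = (t - y * s) / c;
          const double fx = x / h + N / 2;
          if (fx < 0.0 || fx > N - 1) continue;
          const int ix = (int)fx;
          const double w = fx - ix;
          const double lo = img(ix, iy);
          const double hi = (ix + 1 < N) ? img(ix + 1, iy) : 0.0;
          acc += (1.0 - w) * lo + w * hi;
        }
        out(v, d) = acc * step;
      }
    }
  }
  return out;
}

// Back projection of (already filtered) projections with linear detector
// interpolation. Caller applies the pi/n_views angular quadrature factor.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix q, NumericVector angles,
                              int npix, double h, double dd) {
  const int nv = angles.size();
  const int ndet = q.ncol();
  NumericMatrix img(npix, npix);

  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]);
    const double s = std::sin(angles[v]);
    for (int iy = 0; iy < npix; ++iy) {
      const double y = (iy - npix / 2) * h;
      const double base = y * s;
      for (int ix = 0; ix < npix; ++ix) {
        const double x = (ix - npix / 2) * h;
        const double u = (x * c + base) / dd + ndet / 2;
        if (u < 0.0 || u > ndet - 1) continue;
        const int d = (int)u;
        const double w = u - d;
        const double hi = (d + 1 < ndet) ? q(v, d + 1) : 0.0;
        img(ix, iy) += (1.0 - w) * q(v, d) + w * hi;
      }
    }
  }
  return img;
}

// Convolution gridding of radial k-space samples onto an oversampled
// Cartesian grid with a separable kernel given as a lookup table.
//
// sre/sim: [n_views x n_radial] real/imag samples, column j holding radial
// index r = j - n_radial/2 (0-based j, DC at column n_radial/2).
// w: per-sample density-compensation weights (same shape, physical k-area).
// Grid is G x G; a sample at radius r along angle theta lands at
// (G/2 + os*r*cos, G/2 + os*r*sin) in grid cells, os = G/n_radial.
// lut tabulates the kernel on [0, width/2] with lut_scale cells per unit.
// Out-of-range kernel taps wrap modulo G (periodic DFT grid).
// [[Rcpp::export]]
List cpp_grid_radial(NumericMatrix sre, NumericMatrix sim, NumericMatrix w,
                     NumericVector angles, int G, double width,
                     NumericVector lut, double lut_scale) {
  const int nv = sre.nrow();
  const int nr = sre.ncol();
  const double os = (double)G / nr;
  const double halfw = 0.5 * width;
  const int nlut = lut.size();
  NumericMatrix gre(G, G), gim(G, G);
  std::vector<double> wx(16), wy(16);

  for (int v = 0; v < nv; ++v) {
    const double c = std::cos(angles[v]);
    const double s = std::sin(angles[v]);
    for (int j = 0; j < nr; ++j) {
      const double wgt = w(v, j);
      if (wgt == 0.0) continue;
      const double re = sre(v, j) * wgt;
      const double im = sim(v, j) * wgt;
      const double r = (j - nr / 2) * os;
      const double u = G / 2 + r * c;
      const double vv = G / 2 + r * s;
      const int x0 = (int)std::ceil(u - halfw);
      const int x1 = (int)std::floor(u + halfw);
      const int y0 = (int)std::ceil(vv - halfw);
      const int y1 = (int)std::floor(vv + halfw);
      const int nx = x1 - x0 + 1, ny = y1 - y0 + 1;
      for (int i = 0; i < nx; ++i) {
        double a = std::fabs((x0 + i) - u) * lut_scale;
        int ia = (int)a;
        wx[i] = (ia + 1 < nlut) ? lut[ia] + (a - ia) * (lut[ia + 1] - lut[ia]) : 0.0;
      }
      for (int i = 0; i < ny; ++i) {
        double a = std::fabs((y0 + i) - vv) * lut_scale;
        int ia = (int)a;
        wy[i] = (ia + 1 < nlut) ? lut[ia] + (a - ia) * (lut[ia + 1] - lut[ia]) : 0.0;
      }
      for (int iy = 0; iy < ny; ++iy) {
        int gy = (y0 + iy) % G; if (gy < 0) gy += G;
        const double ky = wy[iy];
        if (ky == 0.0) continue;
        for (int ix = 0; ix < nx; ++ix) {
          const double kk = wx[ix] * ky;
          if (kk == 0.0) continue;
          int gx = (x0 + ix) % G; if (gx < 0) gx += G;
          gre(gx, gy) += re * kk;
          gim(gx, gy) += im * kk;
        }
      }
    }
  }
  return List::create(_["re"] = gre, _["im"] = gim);
}
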