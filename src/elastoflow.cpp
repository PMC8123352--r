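// Low-level image kernels: separable Gaussian filtering, bilinear warping,
// image pyramids, dense optical flow (pyramidal Lucas-Kanade and
// Horn-Schunck), and the valid-region cross-correlation used by the
// Savitzky-Golay strain differentiator.
//
// Matrices follow the package convention: row index = axial depth z,
// column index = lateral x. Displacements are in pixels; ux moves along
// columns, uz along rows.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 boundary (no repeated edge sample), safe for any i
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int half = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    k[i + half] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + half];
  }
  for (double& v : k) v /= s;
  return k;
}

static NumericMatrix sep_conv(const NumericMatrix& m, const std::vector<double>& k) {
  int nr = m.nrow(), nc = m.ncol();
  int half = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (axial direction, within each column)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -half; t <= half; ++t)
        acc += k[t + half] * m(reflect_idx(i + t, nr), j);
      tmp(i, j) = acc;
    }
  // along columns (lateral direction, within each row)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -half; t <= half; ++t)
        acc += k[t + half] * tmp(i, reflect_idx(j + t, nc));
      out(i, j) = acc;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  if (sigma <= 0) return clone(img);
  return sep_conv(img, gauss_kernel(sigma));
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int nrOut, int ncOut) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nrOut, ncOut);
  double sr = (double)nr / nrOut, sc = (double)nc / ncOut;
  for (int j = 0; j < ncOut; ++j) {
    double x = (j + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(x);
    double fx = x - j0;
    int ja = std::min(std::max(j0, 0), nc - 1);
    int jb = std::min(std::max(j0 + 1, 0), nc - 1);
    for (int i = 0; i < nrOut; ++i) {
      double z = (i + 0.5) * sr - 0.5;
      int i0 = (int)std::floor(z);
      double fz = z - i0;
      int ia = std::min(std::max(i0, 0), nr - 1);
      int ib = std::min(std::max(i0 + 1, 0), nr - 1);
      out(i, j) = (1 - fz) * ((1 - fx) * img(ia, ja) + fx * img(ia, jb)) +
                  fz * ((1 - fx) * img(ib, ja) + fx * img(ib, jb));
    }
  }
  return out;
}

static NumericMatrix downsample2(const NumericMatrix& img) {
  NumericMatrix b = cpp_gauss_blur(img, 1.0);
  int nr = img.nrow(), nc = img.ncol();
  int nr2 = (nr + 1) / 2, nc2 = (nc + 1) / 2;
  NumericMatrix out(nr2, nc2);
  for (int j = 0; j < nc2; ++j)
    for (int i = 0; i < nr2; ++i)
      out(i, j) = b(std::min(2 * i, nr - 1), std::min(2 * j, nc - 1));
  return out;
}

// Bilinear lookup of img at (row + uz, col + ux); NA outside the domain.
// [[Rcpp::export]]
NumericMatrix cpp_warp_bilinear(const NumericMatrix& img, const NumericMatrix& ux,
                                const NumericMatrix& uz) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double z = i + uz(i, j), x = j + ux(i, j);
      if (ISNAN(z) || ISNAN(x) || z < 0 || x < 0 || z > nr - 1 || x > nc - 1) {
        out(i, j) = NA_REAL;
        continue;
      }
      int i0 = (int)std::floor(z), j0 = (int)std::floor(x);
      if (i0 == nr - 1) i0 = nr - 2;
      if (j0 == nc - 1) j0 = nc - 2;
      double fz = z - i0, fx = x - j0;
      double v00 = img(i0, j0), v01 = img(i0, j0 + 1);
      double v10 = img(i0 + 1, j0), v11 = img(i0 + 1, j0 + 1);
      if (ISNAN(v00) || ISNAN(v01) || ISNAN(v10) || ISNAN(v11)) {
        out(i, j) = NA_REAL;
        continue;
      }
      out(i, j) = (1 - fz) * ((1 - fx) * v00 + fx * v01) +
                  fz * ((1 - fx) * v10 + fx * v11);
    }
  return out;
}

// Border-clamped box sum via an integral image; two passes approximate a
// smooth aggregation window. Used for the Lucas-Kanade normal equations,
// where only the relative weighting across the five moment matrices matters.
static NumericMatrix box_sum(const NumericMatrix& m, int r) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<double> S((nr + 1) * (nc + 1), 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      S[(i + 1) + (j + 1) * (nr + 1)] = m(i, j) + S[i + (j + 1) * (nr + 1)] +
        S[(i + 1) + j * (nr + 1)] - S[i + j * (nr + 1)];
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(j - r, 0), j1 = std::min(j + r, nc - 1) + 1;
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(i - r, 0), i1 = std::min(i + r, nr - 1) + 1;
      out(i, j) = S[i1 + j1 * (nr + 1)] - S[i0 + j1 * (nr + 1)] -
                  S[i1 + j0 * (nr + 1)] + S[i0 + j0 * (nr + 1)];
    }
  }
  return out;
}

static NumericMatrix window_sum(const NumericMatrix& m, int r) {
  return box_sum(box_sum(m, r), r);
}

static void gradients(const NumericMatrix& a, NumericMatrix& gx, NumericMatrix& gz) {
  int nr = a.nrow(), nc = a.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      gz(i, j) = 0.5 * (a(reflect_idx(i + 1, nr), j) - a(reflect_idx(i - 1, nr), j));
      gx(i, j) = 0.5 * (a(i, reflect_idx(j + 1, nc)) - a(i, reflect_idx(j - 1, nc)));
    }
}

static NumericMatrix warp_fill(const NumericMatrix& tgt, const NumericMatrix& ux,
                               const NumericMatrix& uz, const NumericMatrix& ref) {
  NumericMatrix w = cpp_warp_bilinear(tgt, ux, uz);
  int n = w.nrow() * w.ncol();
  for (int k = 0; k < n; ++k)
    if (ISNAN(w[k])) w[k] = ref[k];
  return w;
}

static int n_levels(int nr, int nc, int maxLevels) {
  int n = 1, m = std::min(nr, nc);
  while (n < maxLevels && (m >> n) >= 24) ++n;
  return n;
}

// Pyramidal iterative Lucas-Kanade dense flow with Tikhonov-regularised
// windowed normal equations and light flow smoothing between iterations.
// [[Rcpp::export]]
List cpp_flow_lk(const NumericMatrix& ref, const NumericMatrix& tgt,
                 int maxLevels = 5, int nIter = 5, double sigmaWin = 8.0,
                 double regFactor = 1e-3, double sigmaFlow = 1.0) {
  int nr = ref.nrow(), nc = ref.ncol();
  int nl = n_levels(nr, nc, maxLevels);
  std::vector<NumericMatrix> pr, pt;
  pr.push_back(clone(ref));
  pt.push_back(clone(tgt));
  for (int l = 1; l < nl; ++l) {
    pr.push_back(downsample2(pr[l - 1]));
    pt.push_back(downsample2(pt[l - 1]));
  }
  NumericMatrix ux, uz;
  for (int lev = nl - 1; lev >= 0; --lev) {
    const NumericMatrix &R = pr[lev], &T = pt[lev];
    int r = R.nrow(), c = R.ncol();
    if (lev == nl - 1) {
      ux = NumericMatrix(r, c);
      uz = NumericMatrix(r, c);
    } else {
      ux = cpp_resize_bilinear(ux, r, c);
      uz = cpp_resize_bilinear(uz, r, c);
      for (int k = 0; k < r * c; ++k) { ux[k] *= 2.0; uz[k] *= 2.0; }
    }
    NumericMatrix gxR(r, c), gzR(r, c), gxW(r, c), gzW(r, c);
    gradients(R, gxR, gzR);
    for (int it = 0; it < nIter; ++it) {
      NumericMatrix W = warp_fill(T, ux, uz, R);
      gradients(W, gxW, gzW);
      NumericMatrix G11(r, c), G12(r, c), G22(r, c), B1(r, c), B2(r, c);
      double trace_sum = 0.0;
      for (int k = 0; k < r * c; ++k) {
        double Ix = 0.5 * (gxR[k] + gxW[k]);
        double Iz = 0.5 * (gzR[k] + gzW[k]);
        double It = W[k] - R[k];
        G11[k] = Ix * Ix; G12[k] = Ix * Iz; G22[k] = Iz * Iz;
        B1[k] = Ix * It; B2[k] = Iz * It;
        trace_sum += G11[k] + G22[k];
      }
      int rw = std::max(1, (int)std::lround(sigmaWin));
      G11 = window_sum(G11, rw); G12 = window_sum(G12, rw);
      G22 = window_sum(G22, rw);
      B1 = window_sum(B1, rw); B2 = window_sum(B2, rw);
      // regularisation on the scale of the windowed sums (two box passes
      // carry a total weight of (2 rw + 1)^4)
      double wgain = std::pow(2.0 * rw + 1.0, 4);
      double lambda = regFactor * trace_sum / (r * c) * wgain + 1e-12;
      for (int k = 0; k < r * c; ++k) {
        double a = G11[k] + lambda, b = G12[k], d = G22[k] + lambda;
        double det = a * d - b * b;
        double dux = -(d * B1[k] - b * B2[k]) / det;
        double duz = -(-b * B1[k] + a * B2[k]) / det;
        double mag = std::sqrt(dux * dux + duz * duz);
        if (mag > 2.0) { dux *= 2.0 / mag; duz *= 2.0 / mag; }
        ux[k] += dux; uz[k] += duz;
      }
      if (sigmaFlow > 0) {
        ux = cpp_gauss_blur(ux, sigmaFlow);
        uz = cpp_gauss_blur(uz, sigmaFlow);
      }
    }
  }
  return List::create(_["ux"] = ux, _["uz"] = uz);
}

// Pyramidal Horn-Schunck flow (Jacobi relaxation of the variational
// equations around the current warp).
// [[Rcpp::export]]
List cpp_flow_hs(const NumericMatrix& ref, const NumericMatrix& tgt,
                 int maxLevels = 5, int nWarp = 4, int nRelax = 80,
                 double alpha = 0.08) {
  int nr = ref.nrow(), nc = ref.ncol();
  int nl = n_levels(nr, nc, maxLevels);
  std::vector<NumericMatrix> pr, pt;
  pr.push_back(clone(ref));
  pt.push_back(clone(tgt));
  for (int l = 1; l < nl; ++l) {
    pr.push_back(downsample2(pr[l - 1]));
    pt.push_back(downsample2(pt[l - 1]));
  }
  NumericMatrix ux, uz;
  double a2 = alpha * alpha;
  for (int lev = nl - 1; lev >= 0; --lev) {
    const NumericMatrix &R = pr[lev], &T = pt[lev];
    int r = R.nrow(), c = R.ncol();
    if (lev == nl - 1) {
      ux = NumericMatrix(r, c);
      uz = NumericMatrix(r, c);
    } else {
      ux = cpp_resize_bilinear(ux, r, c);
      uz = cpp_resize_bilinear(uz, r, c);
      for (int k = 0; k < r * c; ++k) { ux[k] *= 2.0; uz[k] *= 2.0; }
    }
    NumericMatrix gx(r, c), gz(r, c);
    for (int w = 0; w < nWarp; ++w) {
      NumericMatrix W = warp_fill(T, ux, uz, R);
      gradients(W, gx, gz);
      NumericMatrix dux(r, c), duz(r, c);
      for (int itr = 0; itr < nRelax; ++itr) {
        NumericMatrix nux(r, c), nuz(r, c);
        for (int j = 0; j < c; ++j)
          for (int i = 0; i < r; ++i) {
            double mx = 0.25 * (dux(reflect_idx(i - 1, r), j) + dux(reflect_idx(i + 1, r), j) +
                                dux(i, reflect_idx(j - 1, c)) + dux(i, reflect_idx(j + 1, c)));
            double mz = 0.25 * (duz(reflect_idx(i - 1, r), j) + duz(reflect_idx(i + 1, r), j) +
                                duz(i, reflect_idx(j - 1, c)) + duz(i, reflect_idx(j + 1, c)));
            double Ix = gx(i, j), Iz = gz(i, j), It = W(i, j) - R(i, j);
            double denom = a2 + Ix * Ix + Iz * Iz;
            double t = (Ix * mx + Iz * mz + It) / denom;
            nux(i, j) = mx - Ix * t;
            nuz(i, j) = mz - Iz * t;
          }
        dux = nux; duz = nuz;
      }
      for (int k = 0; k < r * c; ++k) { ux[k] += dux[k]; uz[k] += duz[k]; }
    }
  }
  return List::create(_["ux"] = ux, _["uz"] = uz);
}

// Separable Savitzky-Golay first derivative: plain sum over the 2M+1
// perpendicular lines, then the linear-ramp correlation along the
// derivative axis with weights 3x / ((2M+1)^2 M (M+1) GS). Identical to the
// full 2D kernel cross-correlation, in O(M) per pixel. alongCols = true
// differentiates along the column (lateral) axis.
// [[Rcpp::export]]
NumericMatrix cpp_sg_derive(const NumericMatrix& field, int M, double gs,
                            bool alongCols) {
  int nr = field.nrow(), nc = field.ncol();
  NumericMatrix acc(nr, nc), out(nr, nc);
  std::fill(acc.begin(), acc.end(), NA_REAL);
  std::fill(out.begin(), out.end(), NA_REAL);
  double norm = 3.0 / ((2.0 * M + 1) * (2.0 * M + 1) * M * (M + 1) * gs);
  if (alongCols) {
    for (int j = 0; j < nc; ++j)
      for (int i = M; i < nr - M; ++i) {
        double s = 0.0; bool ok = true;
        for (int t = -M; t <= M; ++t) {
          double v = field(i + t, j);
          if (ISNAN(v)) { ok = false; break; }
          s += v;
        }
        acc(i, j) = ok ? s : NA_REAL;
      }
    for (int j = M; j < nc - M; ++j)
      for (int i = M; i < nr - M; ++i) {
        double s = 0.0; bool ok = true;
        for (int t = -M; t <= M; ++t) {
          double v = acc(i, j + t);
          if (ISNAN(v)) { ok = false; break; }
          s += t * v;
        }
        out(i, j) = ok ? s * norm : NA_REAL;
      }
  } else {
    for (int j = M; j < nc - M; ++j)
      for (int i = 0; i < nr; ++i) {
        double s = 0.0; bool ok = true;
        for (int t = -M; t <= M; ++t) {
          double v = field(i, j + t);
          if (ISNAN(v)) { ok = false; break; }
          s += v;
        }
        acc(i, j) = ok ? s : NA_REAL;
      }
    for (int j = M; j < nc - M; ++j)
      for (int i = M; i < nr - M; ++i) {
        double s = 0.0; bool ok = true;
        for (int t = -M; t <= M; ++t) {
          double v = acc(i + t, j);
          if (ISNAN(v)) { ok = false; break; }
          s += t * v;
        }
        out(i, j) = ok ? s * norm : NA_REAL;
      }
  }
  return out;
}

// Cross-correlation (no kernel flip) as written in the strain estimator:
// out(i,j) = sum_{x,z} kernel(x,z) * field(i+x, j+z), offsets centred.
// Border entries whose window leaves the field are NA; NA inputs propagate.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr_valid(const NumericMatrix& field, const NumericMatrix& kernel) {
  int nr = field.nrow(), nc = field.ncol();
  int kr = kernel.nrow(), kc = kernel.ncol();
  int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int j = hc; j < nc - hc; ++j)
    for (int i = hr; i < nr - hr; ++i) {
      double acc = 0.0;
      bool ok = true;
      for (int b = -hc; b <= hc && ok; ++b)
        for (int a = -hr; a <= hr; ++a) {
          double v = field(i + a, j + b);
          if (ISNAN(v)) { ok = false; break; }
          acc += kernel(a + hr, b + hc) * v;
        }
      out(i, j) = ok ? acc : NA_REAL;
    }
  return out;
}
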