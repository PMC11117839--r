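#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render anti-aliased Gaussian speckle dots into an h x w image.
// Pixel centres sit at (col + 0.5, row + 0.5) in px coordinates, matching
// the pinhole projection convention on the R side.
// [[Rcpp::export]]
NumericMatrix render_dots_cpp(int h, int w, NumericVector cx,
                              NumericVector cy, NumericVector sigma,
                              NumericVector amp, double background) {
  NumericMatrix img(h, w);
  std::fill(img.begin(), img.end(), background);
  int n = cx.size();
  for (int k = 0; k < n; ++k) {
    double s = sigma[k];
    if (!(s > 0)) continue;
    double inv2s2 = 1.0 / (2.0 * s * s);
    int half = (int)std::ceil(3.0 * s) + 1;
    // dot centre in 0-based pixel-index coordinates
    double xc = cx[k] - 0.5, yc = cy[k] - 0.5;
    int x0 = std::max(0, (int)std::floor(xc) - half);
    int x1 = std::min(w - 1, (int)std::ceil(xc) + half);
    int y0 = std::max(0, (int)std::floor(yc) - half);
    int y1 = std::min(h - 1, (int)std::ceil(yc) + half);
    for (int j = x0; j <= x1; ++j) {
      double dx = j - xc;
      for (int i = y0; i <= y1; ++i) {
        double dy = i - yc;
        img(i, j) += amp[k] * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  for (int i = 0; i < h * w; ++i) {
    if (img[i] > 1.0) img[i] = 1.0;
  }
  return img;
}

static inline double bilin(const NumericMatrix &im, double x, double y) {
  // x: 0-based column index, y: 0-based row index; caller guarantees bounds
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  double fx = x - x0, fy = y - y0;
  double v00 = im(y0, x0), v01 = im(y0, x0 + 1);
  double v10 = im(y0 + 1, x0), v11 = im(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// solve a k x k linear system in place (Gaussian elimination, partial
// pivoting); returns false when singular
static bool solve_lin(double A[6][6], double b[6], double x[6], int k) {
  int piv[6];
  for (int i = 0; i < k; ++i) piv[i] = i;
  for (int c = 0; c < k; ++c) {
    int best = c;
    for (int r = c + 1; r < k; ++r)
      if (std::abs(A[piv[r]][c]) > std::abs(A[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    double d = A[piv[c]][c];
    if (std::abs(d) < 1e-16) return false;
    for (int r = c + 1; r < k; ++r) {
      double f = A[piv[r]][c] / d;
      for (int cc = c; cc < k; ++cc) A[piv[r]][cc] -= f * A[piv[c]][cc];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = k - 1; c >= 0; --c) {
    double s = b[piv[c]];
    for (int cc = c + 1; cc < k; ++cc) s -= A[piv[c]][cc] * x[cc];
    x[c] = s / A[piv[c]][c];
  }
  return true;
}

// Subset-based matching between two grayscale images.
//
// pts:   n x 2 integer grid centres (0-based x = column, y = row).
// init:  n x 2 initial integer displacement guesses.
// For each point: exhaustive zero-normalized cross-correlation (ZNCC)
// search over +/- `search` px around the initial guess, then Gauss-Newton
// subpixel refinement of the zero-normalized SSD with bilinear image
// interpolation.  With `affine = 1` a 6-parameter affine subset warp is
// refined after the translation (for cross-camera matching, where
// perspective distorts the subset); the translation solution is kept if
// the affine step diverges.
//
// Returns n x 4: dx, dy (subpixel), zncc score, status
// (0 ok, 2 low contrast, 3 search-edge, 4 out of bounds).
// [[Rcpp::export]]
NumericMatrix dic_match_cpp(NumericMatrix ref, NumericMatrix def,
                            IntegerMatrix pts, IntegerMatrix init,
                            int subset, int search, double min_sd,
                            int max_iter, int affine = 0) {
  int h = ref.nrow(), w = ref.ncol();
  int n = pts.nrow();
  int half = subset / 2;
  int npix = subset * subset;
  NumericMatrix out(n, 4);
  std::vector<double> F0(npix);

  for (int k = 0; k < n; ++k) {
    int x0 = pts(k, 0), y0 = pts(k, 1);
    out(k, 0) = NA_REAL; out(k, 1) = NA_REAL; out(k, 2) = NA_REAL;
    if (x0 - half < 0 || x0 + half >= w || y0 - half < 0 || y0 + half >= h) {
      out(k, 3) = 4; continue;
    }
    // normalized reference subset: zero mean, unit L2 norm
    double mF = 0;
    for (int j = -half; j <= half; ++j)
      for (int i = -half; i <= half; ++i)
        mF += ref(y0 + i, x0 + j);
    mF /= npix;
    double ssF = 0;
    {
      int idx = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i, ++idx) {
          double v = ref(y0 + i, x0 + j) - mF;
          F0[idx] = v;
          ssF += v * v;
        }
    }
    double sdF = std::sqrt(ssF / (npix - 1));
    if (sdF < min_sd) { out(k, 3) = 2; continue; }
    double nF = std::sqrt(ssF);
    for (int i = 0; i < npix; ++i) F0[i] /= nF;

    // integer ZNCC search
    int ix = init(k, 0), iy = init(k, 1);
    double best = -2.0;
    int bdx = 0, bdy = 0;
    bool found = false;
    for (int dy = iy - search; dy <= iy + search; ++dy) {
      int yy = y0 + dy;
      if (yy - half < 0 || yy + half >= h) continue;
      for (int dx = ix - search; dx <= ix + search; ++dx) {
        int xx = x0 + dx;
        if (xx - half < 0 || xx + half >= w) continue;
        double sG = 0, ssG = 0, sFG = 0;
        int idx = 0;
        for (int j = -half; j <= half; ++j)
          for (int i = -half; i <= half; ++i, ++idx) {
            double g = def(yy + i, xx + j);
            sG += g; ssG += g * g; sFG += F0[idx] * g;
          }
        double varG = ssG - sG * sG / npix;
        if (varG < 1e-12) continue;
        double z = sFG / std::sqrt(varG);  // sum(F0) == 0
        if (z > best) { best = z; bdx = dx; bdy = dy; found = true; }
      }
    }
    if (!found) { out(k, 3) = 4; continue; }
    if (std::abs(bdx - ix) == search || std::abs(bdy - iy) == search) {
      out(k, 0) = bdx; out(k, 1) = bdy; out(k, 2) = best; out(k, 3) = 3;
      continue;
    }

    // Gauss-Newton refinement on zero-normalized SSD
    double px = bdx, py = bdy;
    bool ok = true;
    for (int it = 0; it < max_iter; ++it) {
      double cx0 = x0 + px, cy0 = y0 + py;
      if (cx0 - half < 1.5 || cx0 + half > w - 2.5 ||
          cy0 - half < 1.5 || cy0 + half > h - 2.5) { ok = false; break; }
      double sG = 0, ssG = 0;
      std::vector<double> G(npix), Gx(npix), Gy(npix);
      int idx = 0;
      for (int j = -half; j <= half; ++j)
        for (int i = -half; i <= half; ++i, ++idx) {
          double xs = cx0 + j, ys = cy0 + i;
          double g = bilin(def, xs, ys);
          G[idx] = g; sG += g; ssG += g * g;
          Gx[idx] = 0.5 * (bilin(def, xs + 1, ys) - bilin(def, xs - 1, ys));
          Gy[idx] = 0.5 * (bilin(def, xs, ys + 1) - bilin(def, xs, ys - 1));
        }
      double mG = sG / npix;
      double nG = std::sqrt(ssG - npix * mG * mG);
      if (nG < 1e-12) { ok = false; break; }
      double a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0;
      for (int i = 0; i < npix; ++i) {
        double r = (G[i] - mG) / nG - F0[i];
        double jx = Gx[i] / nG, jy = Gy[i] / nG;
        a11 += jx * jx; a12 += jx * jy; a22 += jy * jy;
        b1 += jx * r; b2 += jy * r;
      }
      double det = a11 * a22 - a12 * a12;
      if (std::abs(det) < 1e-20) { ok = false; break; }
      double dxs = (a22 * b1 - a12 * b2) / det;
      double dys = (a11 * b2 - a12 * b1) / det;
      px -= dxs; py -= dys;
      if (std::abs(px - bdx) > 1.5 || std::abs(py - bdy) > 1.5) {
        ok = false; break;
      }
      if (std::abs(dxs) < 1e-4 && std::abs(dys) < 1e-4) break;
    }
    if (!ok) { px = bdx; py = bdy; }

    // optional affine subset warp:
    //   xs = x0 + tx + (1 + a11) j + a12 i,  ys = y0 + ty + a21 j + (1 + a22) i
    double ap[6] = {px, py, 0, 0, 0, 0};
    bool use_affine = false;
    if (affine) {
      bool aok = true;
      for (int it = 0; it < max_iter && aok; ++it) {
        double ext = half * (1 + std::max(std::abs(ap[2]),
                                          std::abs(ap[5])) +
                             std::max(std::abs(ap[3]), std::abs(ap[4])));
        double cx0 = x0 + ap[0], cy0 = y0 + ap[1];
        if (cx0 - ext < 1.5 || cx0 + ext > w - 2.5 ||
            cy0 - ext < 1.5 || cy0 + ext > h - 2.5) { aok = false; break; }
        std::vector<double> G(npix), Jc[6];
        for (int c = 0; c < 6; ++c) Jc[c].resize(npix);
        double sG = 0, ssG = 0;
        int idx = 0;
        for (int j = -half; j <= half; ++j)
          for (int i = -half; i <= half; ++i, ++idx) {
            double xs = cx0 + (1 + ap[2]) * j + ap[3] * i;
            double ys = cy0 + ap[4] * j + (1 + ap[5]) * i;
            double g = bilin(def, xs, ys);
            double gx = 0.5 * (bilin(def, xs + 1, ys) -
                               bilin(def, xs - 1, ys));
            double gy = 0.5 * (bilin(def, xs, ys + 1) -
                               bilin(def, xs, ys - 1));
            G[idx] = g; sG += g; ssG += g * g;
            Jc[0][idx] = gx;      Jc[1][idx] = gy;
            Jc[2][idx] = gx * j;  Jc[3][idx] = gx * i;
            Jc[4][idx] = gy * j;  Jc[5][idx] = gy * i;
          }
        double mG = sG / npix;
        double nG = std::sqrt(ssG - npix * mG * mG);
        if (nG < 1e-12) { aok = false; break; }
        double A[6][6] = {{0}}, bvec[6] = {0}, dp[6];
        for (int i = 0; i < npix; ++i) {
          double r = (G[i] - mG) / nG - F0[i];
          for (int c = 0; c < 6; ++c) {
            bvec[c] += Jc[c][i] / nG * r;
            for (int c2 = c; c2 < 6; ++c2)
              A[c][c2] += (Jc[c][i] / nG) * (Jc[c2][i] / nG);
          }
        }
        for (int c = 0; c < 6; ++c)
          for (int c2 = 0; c2 < c; ++c2) A[c][c2] = A[c2][c];
        if (!solve_lin(A, bvec, dp, 6)) { aok = false; break; }
        for (int c = 0; c < 6; ++c) ap[c] -= dp[c];
        if (std::abs(ap[0] - px) > 2 || std::abs(ap[1] - py) > 2 ||
            std::abs(ap[2]) > 0.5 || std::abs(ap[3]) > 0.5 ||
            std::abs(ap[4]) > 0.5 || std::abs(ap[5]) > 0.5) {
          aok = false; break;
        }
        if (std::abs(dp[0]) < 1e-4 && std::abs(dp[1]) < 1e-4 &&
            std::abs(dp[2]) < 1e-5 && std::abs(dp[3]) < 1e-5 &&
            std::abs(dp[4]) < 1e-5 && std::abs(dp[5]) < 1e-5) break;
      }
      if (aok) use_affine = true;
    }

    // final ZNCC at the refined position (affine-warped when used)
    double score = best;
    {
      double tx = use_affine ? ap[0] : px, ty = use_affine ? ap[1] : py;
      double cx0 = x0 + tx, cy0 = y0 + ty;
      double ext = half;
      if (use_affine)
        ext = half * (1 + std::max(std::abs(ap[2]), std::abs(ap[5])) +
                      std::max(std::abs(ap[3]), std::abs(ap[4])));
      if (cx0 - ext >= 0.5 && cx0 + ext <= w - 1.5 &&
          cy0 - ext >= 0.5 && cy0 + ext <= h - 1.5) {
        double sG = 0, ssG = 0, sFG = 0;
        int idx = 0;
        for (int j = -half; j <= half; ++j)
          for (int i = -half; i <= half; ++i, ++idx) {
            double xs, ys;
            if (use_affine) {
              xs = cx0 + (1 + ap[2]) * j + ap[3] * i;
              ys = cy0 + ap[4] * j + (1 + ap[5]) * i;
            } else {
              xs = cx0 + j; ys = cy0 + i;
            }
            double g = bilin(def, xs, ys);
            sG += g; ssG += g * g; sFG += F0[idx] * g;
          }
        double varG = ssG - sG * sG / npix;
        if (varG > 1e-12) score = sFG / std::sqrt(varG);
      }
      if (use_affine) { px = ap[0]; py = ap[1]; }
    }
    out(k, 0) = px; out(k, 1) = py; out(k, 2) = score; out(k, 3) = 0;
  }
  return out;
}
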