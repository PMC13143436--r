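#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Windowed block matching between rectified stereo images.
//
// For each processed left-image pixel, the cost of candidate integer
// disparities d in [center - halfwidth, center + halfwidth] is evaluated over
// a circular window; the integer minimum (ties broken toward the smaller
// disparity) is refined by a quadratic fit through its two neighbours.
//
// norm_mode 0: zero-mean SSD divided by the product of window norms,
//              cost = sum((a/|a| - b/|b|)^2) = 2 (1 - ZNCC); invariant to
//              affine intensity maps of either image.
// norm_mode 1: plain SSD divided by left-window energy.
//
// Pixels whose window exits the left image, whose window has zero variance,
// with no in-bounds candidate, or whose cost minimum sits on the search-range
// boundary (no quadratic refinement possible) are masked.
//
// Window pixels are addressed through precomputed linear offsets into the
// column-major image arrays; window-fit checks use the offsets' bounding box.
// [[Rcpp::export(name = ".match_core_cpp")]]
List match_core_cpp(NumericMatrix left, NumericMatrix right,
                    IntegerVector roi, int step,
                    IntegerVector win_dx, IntegerVector win_dy,
                    NumericMatrix center, int halfwidth,
                    int norm_mode, double eps) {
  const int H = left.nrow(), W = left.ncol();
  const int x0 = roi[0], x1 = roi[1], y0 = roi[2], y1 = roi[3]; // 1-based incl.
  const int nw = win_dx.size();
  const int nx = (x1 - x0) / step + 1;
  const int ny = (y1 - y0) / step + 1;
  NumericMatrix disp(ny, nx), cost(ny, nx);
  LogicalMatrix valid(ny, nx), degen(ny, nx);
  std::fill(disp.begin(), disp.end(), NA_REAL);
  std::fill(cost.begin(), cost.end(), NA_REAL);

  const double *pl = left.begin();
  const double *pr = right.begin();
  std::vector<int> loff(nw);
  int dx_min = 0, dx_max = 0, dy_min = 0, dy_max = 0;
  for (int k = 0; k < nw; ++k) {
    loff[k] = win_dx[k] * H + win_dy[k];
    dx_min = std::min(dx_min, (int)win_dx[k]);
    dx_max = std::max(dx_max, (int)win_dx[k]);
    dy_min = std::min(dy_min, (int)win_dy[k]);
    dy_max = std::max(dy_max, (int)win_dy[k]);
  }
  const bool center_scalar = (center.nrow() == 1 && center.ncol() == 1);
  const int ncand = 2 * halfwidth + 1;
  std::vector<double> cvec(ncand);
  std::vector<int> cok(ncand);
  std::vector<double> A(nw);

  for (int iy = 0; iy < ny; ++iy) {
    const int y = y0 + iy * step;       // 1-based
    if (y + dy_min < 1 || y + dy_max > H) continue;
    for (int ix = 0; ix < nx; ++ix) {
      const int x = x0 + ix * step;
      if (x + dx_min < 1 || x + dx_max > W) continue;
      const int p = (x - 1) * H + (y - 1);
      double sumA = 0.0;
      for (int k = 0; k < nw; ++k) {
        A[k] = pl[p + loff[k]];
        sumA += A[k];
      }
      const double meanA = sumA / nw;
      double ssA = 0.0, eA = 0.0;
      for (int k = 0; k < nw; ++k) {
        const double a = A[k] - meanA;
        ssA += a * a;
        eA += A[k] * A[k];
      }
      if ((norm_mode == 0 && ssA < eps) || (norm_mode == 1 && eA < eps))
        continue;  // all-constant window: masked
      const int c0 = (int) std::lround(center_scalar ? center(0, 0)
                                                     : center(iy, ix));
      int best = -1;
      double bestc = R_PosInf;
      for (int j = 0; j < ncand; ++j) {
        const int d = c0 - halfwidth + j;
        const int xr = x - d;
        if (xr + dx_min < 1 || xr + dx_max > W) {
          cok[j] = 0;
          cvec[j] = R_PosInf;
          continue;
        }
        cok[j] = 1;
        const int q = p - d * H;
        double c;
        if (norm_mode == 0) {
          double sumB = 0.0, ssB = 0.0, cross = 0.0;
          for (int k = 0; k < nw; ++k) {
            const double b = pr[q + loff[k]];
            sumB += b;
            ssB += b * b;
            cross += A[k] * b;
          }
          // zero-mean forms from the raw sums
          const double vB = ssB - sumB * sumB / nw;
          const double cAB = cross - meanA * sumB;
          if (vB < eps) { cok[j] = 0; cvec[j] = R_PosInf; continue; }
          c = 2.0 * (1.0 - cAB / std::sqrt(ssA * vB));
        } else {
          double ssd = 0.0;
          for (int k = 0; k < nw; ++k) {
            const double dv = A[k] - pr[q + loff[k]];
            ssd += dv * dv;
          }
          c = ssd / eA;
        }
        cvec[j] = c;
        // strict less-than keeps the first (smallest-disparity) minimum on ties
        if (c < bestc) { bestc = c; best = j; }
      }
      if (best < 0) continue;
      if (best == 0 || best == ncand - 1 || !cok[best - 1] || !cok[best + 1])
        continue;  // boundary minimum: degenerate cost curve, masked
      const double cm = cvec[best - 1], cc = cvec[best], cp = cvec[best + 1];
      const double denom = cm - 2.0 * cc + cp;
      double delta;
      bool dg = false;
      if (cc <= 1e-9) { delta = 0.0; }  // numerically exact integer match
      else if (denom <= 0 || !R_finite(denom)) { delta = 0.0; dg = true; }
      else {
        delta = (cm - cp) / (2.0 * denom);
        if (delta <= -1.0) delta = -(1.0 - 1e-9);
        if (delta >= 1.0) delta = 1.0 - 1e-9;
      }
      disp(iy, ix) = (double)(c0 - halfwidth + best) + delta;
      cost(iy, ix) = cc;
      valid(iy, ix) = true;
      degen(iy, ix) = dg;
    }
  }
  return List::create(_["disparity"] = disp, _["valid"] = valid,
                      _["cost"] = cost, _["degenerate"] = degen);
}

// Cost curve at a single pixel over the full candidate range (diagnostics and
// brute-force comparison of the integer matching stage).
// [[Rcpp::export(name = ".match_cost_curve_cpp")]]
NumericVector match_cost_curve_cpp(NumericMatrix left, NumericMatrix right,
                                   int x, int y,
                                   IntegerVector win_dx, IntegerVector win_dy,
                                   IntegerVector cands, int norm_mode,
                                   double eps) {
  const int H = left.nrow(), W = left.ncol();
  const int nw = win_dx.size();
  NumericVector out(cands.size(), NA_REAL);
  std::vector<double> A(nw);
  double sumA = 0.0;
  for (int k = 0; k < nw; ++k) {
    int xx = x + win_dx[k], yy = y + win_dy[k];
    if (xx < 1 || xx > W || yy < 1 || yy > H) return out;
    A[k] = left(yy - 1, xx - 1);
    sumA += A[k];
  }
  const double meanA = sumA / nw;
  double ssA = 0.0, eA = 0.0;
  for (int k = 0; k < nw; ++k) {
    double a = A[k] - meanA;
    ssA += a * a;
    eA += A[k] * A[k];
  }
  for (int j = 0; j < cands.size(); ++j) {
    const int d = cands[j];
    bool ok = true;
    double sumB = 0.0;
    std::vector<double> B(nw);
    for (int k = 0; k < nw && ok; ++k) {
      int xx = x - d + win_dx[k], yy = y + win_dy[k];
      if (xx < 1 || xx > W || yy < 1 || yy > H) { ok = false; break; }
      B[k] = right(yy - 1, xx - 1);
      sumB += B[k];
    }
    if (!ok) continue;
    if (norm_mode == 0) {
      const double meanB = sumB / nw;
      double ssB = 0.0, cross = 0.0;
      for (int k = 0; k < nw; ++k) {
        double b = B[k] - meanB;
        ssB += b * b;
        cross += (A[k] - meanA) * b;
      }
      if (ssA < eps || ssB < eps) continue;
      out[j] = 2.0 * (1.0 - cross / std::sqrt(ssA * ssB));
    } else {
      double ssd = 0.0;
      for (int k = 0; k < nw; ++k) {
        double dv = A[k] - B[k];
        ssd += dv * dv;
      }
      if (eA < eps) continue;
      out[j] = ssd / eA;
    }
  }
  return out;
}
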