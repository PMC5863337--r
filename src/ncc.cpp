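// Normalized cross-correlation block matching for speckle tracking.
// One tracking step: propagate N points from the previous frame into the
// current one, scoring candidate displacements by a blend of the
// previous-frame template and the frame-0 template (drift control), with
// parabolic sub-pixel refinement of the correlation peak.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double ncc(const NumericMatrix &img, int cy, int cx,
                         const std::vector<double> &tmpl, double tmean,
                         double tss, int b) {
  // tmpl is the (2b+1)^2 template, row-major; returns NCC in [-1, 1]
  const int n = (2 * b + 1) * (2 * b + 1);
  double s = 0.0, ss = 0.0, sc = 0.0;
  int k = 0;
  for (int dy = -b; dy <= b; ++dy) {
    for (int dx = -b; dx <= b; ++dx, ++k) {
      double v = img(cy + dy, cx + dx);
      s += v;
      ss += v * v;
      sc += v * tmpl[k];
    }
  }
  double pmean = s / n;
  double pvar = ss - n * pmean * pmean;
  if (pvar <= 1e-12 || tss <= 1e-12) return 0.0;
  double cov = sc - n * pmean * tmean;
  return cov / std::sqrt(pvar * tss);
}

static void grab(const NumericMatrix &img, int cy, int cx, int b,
                 std::vector<double> &tmpl, double &tmean, double &tss) {
  const int n = (2 * b + 1) * (2 * b + 1);
  tmpl.resize(n);
  double s = 0.0, ss = 0.0;
  int k = 0;
  for (int dy = -b; dy <= b; ++dy)
    for (int dx = -b; dx <= b; ++dx, ++k) {
      double v = img(cy + dy, cx + dx);
      tmpl[k] = v;
      s += v;
      ss += v * v;
    }
  tmean = s / n;
  tss = ss - n * tmean * tmean;
}

static inline double para(double ym, double y0, double yp) {
  double den = ym - 2.0 * y0 + yp;
  if (std::fabs(den) < 1e-12) return 0.0;
  double off = 0.5 * (ym - yp) / den;
  if (off > 0.5) off = 0.5;
  if (off < -0.5) off = -0.5;
  return off;
}

// [[Rcpp::export(name = ".ncc_step")]]
NumericMatrix ncc_step(NumericMatrix prev, NumericMatrix cur,
                       NumericMatrix ref, NumericMatrix pts_prev,
                       NumericMatrix pts_ref, int block, int search,
                       double blend) {
  const int H = cur.nrow(), W = cur.ncol();
  const int b = block / 2;
  const int n = pts_prev.nrow();
  NumericMatrix out(n, 3);
  std::vector<double> tp, tr;
  const int S = 2 * search + 1;
  std::vector<double> score(S * S);

  for (int i = 0; i < n; ++i) {
    int cy = (int)std::lround(pts_prev(i, 0)) - 1; // 1-based in, 0-based here
    int cx = (int)std::lround(pts_prev(i, 1)) - 1;
    int ry = (int)std::lround(pts_ref(i, 0)) - 1;
    int rx = (int)std::lround(pts_ref(i, 1)) - 1;
    // clamp template centres so the block fits
    cy = std::min(std::max(cy, b), H - 1 - b);
    cx = std::min(std::max(cx, b), W - 1 - b);
    ry = std::min(std::max(ry, b), H - 1 - b);
    rx = std::min(std::max(rx, b), W - 1 - b);
    double pmean, pss, rmean, rss;
    grab(prev, cy, cx, b, tp, pmean, pss);
    grab(ref, ry, rx, b, tr, rmean, rss);

    double best = -2.0;
    int bdy = 0, bdx = 0;
    for (int dy = -search; dy <= search; ++dy) {
      for (int dx = -search; dx <= search; ++dx) {
        int yy = cy + dy, xx = cx + dx;
        double sc;
        if (yy < b || yy > H - 1 - b || xx < b || xx > W - 1 - b) {
          sc = -2.0;
        } else {
          sc = blend * ncc(cur, yy, xx, tp, pmean, pss, b) +
               (1.0 - blend) * ncc(cur, yy, xx, tr, rmean, rss, b);
        }
        score[(dy + search) * S + (dx + search)] = sc;
        if (sc > best) {
          best = sc;
          bdy = dy;
          bdx = dx;
        }
      }
    }
    double offy = 0.0, offx = 0.0;
    int iy = bdy + search, ix = bdx + search;
    // a (numerically) perfect match needs no sub-pixel refinement; the
    // parabola vertex would otherwise be pulled off-centre by asymmetric
    // neighbour correlations
    if (best > 0.9999) {
      out(i, 0) = pts_prev(i, 0) + bdy;
      out(i, 1) = pts_prev(i, 1) + bdx;
      out(i, 2) = best;
      continue;
    }
    if (iy > 0 && iy < S - 1) {
      double a = score[(iy - 1) * S + ix], c = score[(iy + 1) * S + ix];
      if (a > -1.5 && c > -1.5) offy = para(a, best, c);
    }
    if (ix > 0 && ix < S - 1) {
      double a = score[iy * S + ix - 1], c = score[iy * S + ix + 1];
      if (a > -1.5 && c > -1.5) offx = para(a, best, c);
    }
    // the template anchored at the rounded centre moved by (bdy, bdx) +
    // sub-pixel offset; apply that displacement to the unrounded input
    // position so fractional coordinates are preserved across frames
    out(i, 0) = pts_prev(i, 0) + bdy + offy;
    out(i, 1) = pts_prev(i, 1) + bdx + offx;
    out(i, 2) = best;
  }
  return out;
}
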