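#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2D median filter with edge replication.  k must be odd; the window is
// k x k centred on each pixel, out-of-frame samples replicate the border.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int k) {
  if (k < 3 || k % 2 == 0)
    stop("kernel size must be an odd integer >= 3");
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  int mid = (k * k) / 2; // k*k odd -> exact middle order statistic
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = clampi(j + dj, 0, nc - 1);
        for (int di = -h; di <= h; ++di) {
          buf[m++] = x(clampi(i + di, 0, nr - 1), cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Exhaustive normalized cross-correlation search.  The template (odd
// dimensions) is compared against every placement whose centre lies within
// +/- half pixels of (cr, cc); placements clipped by the frame are skipped.
// Returns the best centre (0-based) and its correlation score.
// [[Rcpp::export]]
List ncc_search_cpp(NumericMatrix img, NumericMatrix templ, int cr, int cc,
                    int half) {
  int tr = templ.nrow(), tc = templ.ncol();
  if (tr % 2 == 0 || tc % 2 == 0)
    stop("template dimensions must be odd");
  int hr = tr / 2, hc = tc / 2;
  int nr = img.nrow(), nc = img.ncol();
  int n = tr * tc;
  double tmean = 0.0;
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) tmean += templ(i, j);
  tmean /= n;
  double tss = 0.0;
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) {
      double d = templ(i, j) - tmean;
      tss += d * d;
    }
  double best = -2.0;
  int br = cr, bc = cc;
  for (int dr = -half; dr <= half; ++dr) {
    int r = cr + dr;
    if (r - hr < 0 || r + hr >= nr) continue;
    for (int dc = -half; dc <= half; ++dc) {
      int c = cc + dc;
      if (c - hc < 0 || c + hc >= nc) continue;
      double imean = 0.0;
      for (int j = -hc; j <= hc; ++j)
        for (int i = -hr; i <= hr; ++i) imean += img(r + i, c + j);
      imean /= n;
      double iss = 0.0, cross = 0.0;
      for (int j = -hc; j <= hc; ++j)
        for (int i = -hr; i <= hr; ++i) {
          double di = img(r + i, c + j) - imean;
          double dt = templ(i + hr, j + hc) - tmean;
          iss += di * di;
          cross += di * dt;
        }
      double denom = std::sqrt(iss * tss);
      double score = denom > 0 ? cross / denom : 0.0;
      if (score > best) {
        best = score;
        br = r;
        bc = c;
      }
    }
  }
  return List::create(Named("row") = br, Named("col") = bc,
                      Named("score") = best);
}
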