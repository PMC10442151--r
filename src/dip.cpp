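#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

// Dip statistic, split-fit convention (see R documentation of
// dipStatistic).
//
// The statistic is the smallest epsilon for which, at some split point
// x_j, the ecdf left of the split admits a convex nondecreasing fit
// within a sup-norm band of half-width epsilon and the part from the
// split onward admits a concave fit (mode atom free at the split).
// The band feasibility decomposes into two independent hull conditions:
//
//   left  (convex)  side: the greatest convex minorant of the points
//         (x_t, a_t), t < j, must not fall more than 2*eps below b_t,
//   right (concave) side: the least concave majorant of the points
//         (x_t, b_t), t >= j, must not rise more than 2*eps above a_t
//         for t > j,
//
// where a_t and b_t are the lower/upper ecdf step values at x_t (ties
// collapsed).  The dip is half the minimum over mode positions of the
// larger of the two hull deviations.  O(m^2) with incremental hulls.

static inline double cross3(double x0, double y0, double x1, double y1,
                            double x2, double y2) {
  return (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
}

// [[Rcpp::export]]
double cpp_dip(Rcpp::NumericVector xin) {
  const int n = xin.size();
  if (n <= 1) return 0.0;
  std::vector<double> x(xin.begin(), xin.end());
  std::sort(x.begin(), x.end());

  // collapse ties: v = unique values, a = ecdf just below, b = ecdf at value
  std::vector<double> v, a, b;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    v.push_back(x[i]);
    a.push_back(static_cast<double>(i) / n);
    b.push_back(static_cast<double>(j + 1) / n);
    i = j + 1;
  }
  const int m = static_cast<int>(v.size());
  if (m == 1) return 0.0;

  // devL[k] = max over t<=k of b_t - GCM(v_t), hull over points 1..k (1-based)
  std::vector<double> devL(m + 1, 0.0), devR(m + 2, 0.0);
  {
    std::vector<int> hull;
    for (int k = 0; k < m; ++k) {
      while (hull.size() >= 2 &&
             cross3(v[hull[hull.size() - 2]], a[hull[hull.size() - 2]],
                    v[hull.back()], a[hull.back()], v[k], a[k]) <= 0.0)
        hull.pop_back();
      hull.push_back(k);
      // evaluate hull at all t <= k (two-pointer walk)
      double mx = 0.0;
      size_t seg = 0;
      for (int t = 0; t <= k; ++t) {
        while (seg + 1 < hull.size() && v[hull[seg + 1]] < v[t]) ++seg;
        double hv;
        if (seg + 1 >= hull.size()) {
          hv = a[hull[seg]];
        } else {
          const int p = hull[seg], q = hull[seg + 1];
          hv = (v[q] == v[p]) ? a[p]
             : a[p] + (a[q] - a[p]) * (v[t] - v[p]) / (v[q] - v[p]);
        }
        const double d = b[t] - hv;
        if (d > mx) mx = d;
      }
      devL[k + 1] = mx;
    }
  }
  {
    std::vector<int> hull;  // concave (upper) hull built right-to-left
    for (int k = m - 1; k >= 0; --k) {
      while (hull.size() >= 2 &&
             cross3(v[hull[hull.size() - 2]], b[hull[hull.size() - 2]],
                    v[hull.back()], b[hull.back()], v[k], b[k]) <= 0.0)
        hull.pop_back();
      hull.push_back(k);
      // deviations at t > k only (anchor point k itself is exempt: the
      // mode atom absorbs the jump there)
      double mx = 0.0;
      size_t seg = 0;  // hull stored right-to-left: hull[0] = rightmost
      for (int t = m - 1; t > k; --t) {
        while (seg + 1 < hull.size() && v[hull[seg + 1]] > v[t]) ++seg;
        double hv;
        if (seg + 1 >= hull.size()) {
          hv = b[hull[seg]];
        } else {
          const int p = hull[seg], q = hull[seg + 1];
          hv = (v[q] == v[p]) ? b[p]
             : b[p] + (b[q] - b[p]) * (v[t] - v[p]) / (v[q] - v[p]);
        }
        const double d = hv - a[t];
        if (d > mx) mx = d;
      }
      devR[k + 1] = mx;
    }
  }

  double best = R_PosInf;
  for (int j = 1; j <= m; ++j) {
    const double e = std::max(devL[j - 1], devR[j]);
    if (e < best) best = e;
  }
  return 0.5 * best;
}
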