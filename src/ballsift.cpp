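#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Rolling-ball tangibility engine.
//
// Points are (i, y[i]) with unit x spacing (the caller pre-scales amplitudes).
// A point is "touchable from above" by a ball of radius r when some disc of
// radius r passes through the point, has its centre on or above the
// horizontal line through the point, and contains no other data point
// strictly in its interior.  Candidate centres for point i lie on the circle
// of radius r around it; every other point j closer than 2r excludes an open
// arc of that circle.  The point is touchable iff the exclusion arcs fail to
// cover the closed upper semicircle [0, pi] of centre directions.

namespace {

struct Arc { double a, b; };

const double PI_ = 3.14159265358979323846;

bool touchable_above(const std::vector<double>& y, int i, double r,
                     std::vector<Arc>& buf) {
  const int n = static_cast<int>(y.size());
  const double two_r = 2.0 * r;
  const double two_r2 = two_r * two_r;
  const int W = static_cast<int>(std::ceil(two_r));
  const double yi = y[i];
  buf.clear();
  const int j0 = std::max(0, i - W), j1 = std::min(n - 1, i + W);
  for (int j = j0; j <= j1; ++j) {
    if (j == i) continue;
    const double dx = static_cast<double>(j - i);
    const double dy = y[j] - yi;
    const double d2 = dx * dx + dy * dy;
    if (d2 >= two_r2) continue;
    const double d = std::sqrt(d2);
    const double phi = std::atan2(dy, dx);
    const double psi = std::acos(d / two_r);
    const double lo = phi - psi, hi = phi + psi;
    // arcs may wrap around +-pi; consider the three unwrapped copies that
    // can intersect [0, pi]
    for (int s = -1; s <= 1; ++s) {
      const double a = lo + s * 2.0 * PI_;
      const double b = hi + s * 2.0 * PI_;
      if (b > 0.0 && a < PI_) buf.push_back(Arc{a, b});
    }
  }
  if (buf.empty()) return true;
  std::sort(buf.begin(), buf.end(),
            [](const Arc& u, const Arc& v) { return u.a < v.a; });
  // sweep: open arcs cover the closed interval [0, pi]?
  double cur = 0.0, maxb = -HUGE_VAL;
  std::size_t k = 0;
  for (;;) {
    while (k < buf.size() && buf[k].a < cur) {
      if (buf[k].b > maxb) maxb = buf[k].b;
      ++k;
    }
    if (maxb <= cur) return true;  // direction angle `cur` is uncovered
    cur = maxb;
    if (cur > PI_) return false;   // semicircle fully covered
  }
}

}  // namespace

// Indicator of ball tangibility from above for every sample.
// [[Rcpp::export]]
LogicalVector rb_touch_above(NumericVector y, double r) {
  const int n = y.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<Arc> buf;
  buf.reserve(256);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = touchable_above(yy, i, r, buf);
  return out;
}

// Maximal tangent radius from above for every sample: the supremum of ball
// radii that can still touch the point.  Radii above r_cap are reported as
// +Inf (convex-hull-exposed points genuinely are +Inf; near-degenerate
// interior points saturate at the cap).  Located by bisection on the
// monotone tangibility predicate: any x spacing of 1 guarantees tangibility
// for r < 1/2, so [0.49, r_cap] always brackets the threshold.
// [[Rcpp::export]]
NumericVector rb_tangent_radius_above(NumericVector y, double r_cap,
                                      double rel_tol) {
  const int n = y.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<Arc> buf;
  buf.reserve(256);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (touchable_above(yy, i, r_cap, buf)) {
      out[i] = R_PosInf;
      continue;
    }
    double lo = 0.49, hi = r_cap;
    for (int it = 0; it < 200 && (hi - lo) > rel_tol * lo; ++it) {
      const double mid = std::sqrt(lo * hi);
      if (touchable_above(yy, i, mid, buf)) lo = mid; else hi = mid;
    }
    out[i] = 0.5 * (lo + hi);
  }
  return out;
}
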