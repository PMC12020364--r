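#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic.
//
// The dip of an empirical distribution function F_n is the smallest d such
// that some unimodal distribution function G (convex below its mode, concave
// above it, an atom at the mode is allowed) satisfies sup_x |F_n - G| <= d.
//
// Computed by iterative refinement of the modal interval: on the current
// interval the greatest convex minorant (GCM) of the lower ECDF corners and
// the least concave majorant (LCM) of the upper corners are built; the
// largest vertical gap between the two hulls proposes a narrower modal
// interval, and the ECDF deviations from the hulls outside that proposal are
// accumulated (a convex/concave fit can split a deviation of D count units
// into D/2 on either side, whence the final division by 2n).
//
// All interior arithmetic is in count units on the blocks of tied values;
// ties outside the modal interval therefore contribute their full block size,
// while an atom at the mode costs nothing (a unimodal G may jump there).

namespace {

struct Blocks {
  std::vector<double> u;   // unique sorted values
  std::vector<double> cum; // cumulative counts, cum[k] = #{x <= u[k]}, 1-based into u
};

Blocks make_blocks(const double* x, int n) {
  Blocks b;
  b.u.reserve(n);
  b.cum.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (b.u.empty() || x[i] != b.u.back()) {
      b.u.push_back(x[i]);
      b.cum.push_back(i + 1.0);
    } else {
      b.cum.back() = i + 1.0;
    }
  }
  return b;
}

// lower hull of points (u[k], lowc(k)) for k in [lo, hi]; returns vertex ids
inline void lower_hull(const Blocks& b, int lo, int hi, std::vector<int>& v) {
  v.clear();
  const std::vector<double>& u = b.u;
  for (int k = lo; k <= hi; ++k) {
    double yk = (k == 0) ? 0.0 : b.cum[k - 1]; // lower corner count
    while (v.size() >= 2) {
      int j = v[v.size() - 1], i = v[v.size() - 2];
      double yj = (j == 0) ? 0.0 : b.cum[j - 1];
      double yi = (i == 0) ? 0.0 : b.cum[i - 1];
      // drop j if it lies on/above chord i -> k
      if ((yj - yi) * (u[k] - u[i]) >= (yk - yi) * (u[j] - u[i]))
        v.pop_back();
      else
        break;
    }
    v.push_back(k);
  }
}

// upper hull of points (u[k], cum[k]) for k in [lo, hi]
inline void upper_hull(const Blocks& b, int lo, int hi, std::vector<int>& v) {
  v.clear();
  const std::vector<double>& u = b.u;
  for (int k = lo; k <= hi; ++k) {
    double yk = b.cum[k];
    while (v.size() >= 2) {
      int j = v[v.size() - 1], i = v[v.size() - 2];
      double yj = b.cum[j], yi = b.cum[i];
      // drop j if it lies on/below chord i -> k
      if ((yj - yi) * (u[k] - u[i]) <= (yk - yi) * (u[j] - u[i]))
        v.pop_back();
      else
        break;
    }
    v.push_back(k);
  }
}

inline double interp(double x0, double y0, double x1, double y1, double x) {
  if (x1 == x0) return y0;
  return y0 + (y1 - y0) * (x - x0) / (x1 - x0);
}

// dip in count units on blocks [implied 2n division by caller]; also returns
// the modal interval as block ids
double dip_blocks(const Blocks& b, int& mlo, int& mhi) {
  const int K = (int)b.u.size();
  int lo = 0, hi = K - 1;
  double dipc = 1.0; // floor: one count split across the two sides
  std::vector<int> g, l;
  int guard = 2 * K + 10;
  while (guard-- > 0) {
    if (lo >= hi) break;
    lower_hull(b, lo, hi, g);
    upper_hull(b, lo, hi, l);

    // largest gap between hulls, evaluated at every vertex of either hull;
    // ties prefer the narrowest proposed modal interval
    double d = -1.0;
    int plo = lo, phi = hi;
    {
      size_t jl = 0; // index into l such that segment [l[jl], l[jl+1]] covers
      for (size_t ig = 0; ig < g.size(); ++ig) {
        int k = g[ig];
        while (jl + 1 < l.size() && l[jl + 1] < k) ++jl;
        double lk;
        int cover_hi;
        if (l[jl] == k || jl + 1 >= l.size()) {
          lk = b.cum[k];
          cover_hi = k;
        } else {
          int a = l[jl], bb = l[jl + 1];
          lk = interp(b.u[a], b.cum[a], b.u[bb], b.cum[bb], b.u[k]);
          cover_hi = bb;
        }
        double lowk = (k == 0) ? 0.0 : b.cum[k - 1];
        double gap = lk - lowk;
        int span = cover_hi - k;
        if (gap > d + 1e-12 || (gap > d - 1e-12 && span < phi - plo)) {
          d = std::max(gap, d);
          plo = k;
          phi = cover_hi;
        }
      }
      size_t jg = 0;
      for (size_t il = 0; il < l.size(); ++il) {
        int k = l[il];
        while (jg + 1 < g.size() && g[jg + 1] < k) ++jg;
        double gk;
        int cover_lo;
        if (g[jg] == k && jg + 1 >= g.size()) {
          gk = (k == 0) ? 0.0 : b.cum[k - 1];
          cover_lo = k;
        } else if (jg + 1 < g.size() && g[jg + 1] >= k && g[jg] <= k && g[jg] < k) {
          int a = g[jg], bb = g[jg + 1];
          gk = interp(b.u[a], (a == 0) ? 0.0 : b.cum[a - 1], b.u[bb],
                      (bb == 0) ? 0.0 : b.cum[bb - 1], b.u[k]);
          cover_lo = a;
        } else { // vertex shared with lower hull
          gk = (k == 0) ? 0.0 : b.cum[k - 1];
          cover_lo = k;
        }
        double gap = b.cum[k] - gk;
        int span = k - cover_lo;
        if (gap > d + 1e-12 || (gap > d - 1e-12 && span < phi - plo)) {
          d = std::max(gap, d);
          plo = cover_lo;
          phi = k;
        }
      }
    }

    if (d <= dipc) break;

    // deviation of the ECDF above the GCM on [lo, plo]; the mode may sit at
    // plo itself, so the jump of plo's tie block is not charged here
    double dip_l = 1.0;
    for (size_t s = 0; s + 1 < g.size() && g[s] < plo; ++s) {
      int jb = g[s], je = g[s + 1];
      if (je > plo) break;
      double yb = (jb == 0) ? 0.0 : b.cum[jb - 1];
      double ye = (je == 0) ? 0.0 : b.cum[je - 1];
      for (int k = jb; k <= je; ++k) {
        if (k == plo) continue;
        double t = b.cum[k] - interp(b.u[jb], yb, b.u[je], ye, b.u[k]);
        if (t > dip_l) dip_l = t;
      }
    }
    // deviation of the ECDF below the LCM on [phi, hi]; phi's own jump may be
    // absorbed by the mode
    double dip_u = 1.0;
    for (size_t s = 0; s + 1 < l.size(); ++s) {
      int jb = l[s], je = l[s + 1];
      if (je <= phi) continue;
      if (jb < phi) continue;
      for (int k = jb; k <= je; ++k) {
        if (k == phi) continue;
        double lowk = (k == 0) ? 0.0 : b.cum[k - 1];
        double t = interp(b.u[jb], b.cum[jb], b.u[je], b.cum[je], b.u[k]) - lowk;
        if (t > dip_u) dip_u = t;
      }
    }

    if (dip_l > dipc) dipc = dip_l;
    if (dip_u > dipc) dipc = dip_u;
    if (plo == lo && phi == hi) { // no refinement possible; gap is resolved
      break;
    }
    lo = plo;
    hi = phi;
  }
  mlo = lo;
  mhi = hi;
  return dipc;
}

double dip_of_sorted(const double* x, int n, double& xlo, double& xhi) {
  Blocks b = make_blocks(x, n);
  if (b.u.size() == 1) { // point mass: degenerate, unimodal by convention
    xlo = xhi = b.u[0];
    return 0.5 / n;
  }
  int mlo, mhi;
  double dipc = dip_blocks(b, mlo, mhi);
  xlo = b.u[mlo];
  xhi = b.u[mhi];
  return dipc / (2.0 * n);
}

} // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
List dip_stat_cpp(NumericVector x) {
  int n = x.size();
  if (n < 4) stop("dip statistic requires n >= 4");
  std::vector<double> xs(x.begin(), x.end());
  for (double v : xs)
    if (!R_finite(v)) stop("dip statistic requires finite values");
  std::sort(xs.begin(), xs.end());
  double xlo, xhi;
  double d = dip_of_sorted(xs.data(), n, xlo, xhi);
  return List::create(_["dip"] = d, _["modal_lo"] = xlo, _["modal_hi"] = xhi,
                      _["degenerate"] = (xs.front() == xs.back()));
}

// Null dips: B samples of size n from uniform(0,1), using R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int B) {
  if (n < 4) stop("dip statistic requires n >= 4");
  if (B < 1) stop("B must be positive");
  NumericVector out(B);
  std::vector<double> buf(n);
  RNGScope scope;
  double xlo, xhi;
  for (int r = 0; r < B; ++r) {
    for (int i = 0; i < n; ++i) buf[i] = unif_rand();
    std::sort(buf.begin(), buf.end());
    out[r] = dip_of_sorted(buf.data(), n, xlo, xhi);
  }
  return out;
}
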