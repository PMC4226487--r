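// Genome-scan statistics: composite-likelihood-ratio sweep scan against the
// background site frequency spectrum, and the omega linkage-disequilibrium
// statistic maximized over split points and window extents.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// q[e][k]: probability that a site with background-spectrum ancestral
// configuration of e escapees + 1 swept lineage shows derived count k in the
// present sample of n (k = 0..n kept; polymorphism conditioning happens in
// the mixture). b_full has length n+1 with mass only on 1..n-1.
std::vector<std::vector<double>> escape_class_probs(
    const std::vector<double>& b_full, int n) {
  // log-binomials
  std::vector<std::vector<double>> lch(n + 2, std::vector<double>(n + 2, 0.0));
  for (int i = 0; i <= n + 1; ++i)
    for (int j = 0; j <= i; ++j)
      lch[i][j] = R::lchoose((double)i, (double)j);
  std::vector<std::vector<double>> q(n + 1, std::vector<double>(n + 1, 0.0));
  for (int e = 0; e <= n; ++e) {
    if (e == n) {
      // everyone escapes: the swept ancestor leaves no descendants and the
      // configuration is the background itself
      for (int k = 0; k <= n; ++k) q[e][k] = b_full[k];
      continue;
    }
    int m = e + 1;
    // downsample the background from n to m (classes 0 and m retained)
    std::vector<double> Bm(m + 1, 0.0);
    for (int j = 0; j <= n; ++j) {
      if (b_full[j] <= 0) continue;
      for (int jp = std::max(0, m - (n - j)); jp <= std::min(m, j); ++jp) {
        double lp = lch[j][jp] + lch[n - j][m - jp] - lch[n][m];
        Bm[jp] += b_full[j] * std::exp(lp);
      }
    }
    // one of the m lineages is the swept ancestor (uniformly); its allele is
    // inherited by the n - e collapsed lineages
    for (int jp = 0; jp <= m; ++jp) {
      if (Bm[jp] <= 0) continue;
      double p_swept_derived = (double)jp / m;
      if (jp >= 1) {
        int k = (jp - 1) + (n - e);
        q[e][k] += Bm[jp] * p_swept_derived;
      }
      if (jp <= m - 1) {
        q[e][jp] += Bm[jp] * (1.0 - p_swept_derived);
      }
    }
  }
  return q;
}

}  // namespace

// Full conditional distribution over derived counts k = 1..n-1 for a site at
// distance d from the putative sweep, with sweep intensity alpha per bp and
// polymorphic background spectrum b (length n-1, classes 1..n-1).
// alpha * d = Inf reproduces the background exactly.
// [[Rcpp::export(name = ".cpp_sweep_site_distribution")]]
NumericVector cpp_sweep_site_distribution(NumericVector b, int n,
                                          double alpha, double d) {
  if ((int)b.size() != n - 1) stop("background spectrum must have length n - 1");
  std::vector<double> b_full(n + 1, 0.0);
  double tot = 0.0;
  for (int k = 1; k <= n - 1; ++k) { b_full[k] = b[k - 1]; tot += b[k - 1]; }
  if (tot <= 0) stop("background spectrum is empty");
  for (int k = 1; k <= n - 1; ++k) b_full[k] /= tot;
  auto q = escape_class_probs(b_full, n);
  double ad = alpha * d;
  double pe = R_finite(ad) ? -std::expm1(-ad) : 1.0;
  // binomial weights over e
  std::vector<double> w(n + 1, 0.0);
  for (int e = 0; e <= n; ++e)
    w[e] = R::dbinom((double)e, (double)n, pe, 0);
  NumericVector out(n - 1);
  double norm = 0.0;
  for (int e = 0; e <= n; ++e)
    norm += w[e] * (1.0 - q[e][0] - q[e][n]);
  for (int k = 1; k <= n - 1; ++k) {
    double s = 0.0;
    for (int e = 0; e <= n; ++e) s += w[e] * q[e][k];
    out[k - 1] = (norm > 0) ? s / norm : 0.0;
  }
  return out;
}

// Composite-likelihood-ratio profile.
// pos: site positions (bp); kcnt: derived counts (1..n-1); b: polymorphic
// background spectrum (length n-1, normalized upstream); grid: test
// positions; alpha_grid: finite sweep intensities (alpha = Inf, i.e. the
// null, is always included so the profile is non-negative).
// Returns a list with the per-position statistic and the maximizing alpha
// (Inf when the null maximizes).
// [[Rcpp::export(name = ".cpp_clr_scan")]]
List cpp_clr_scan(NumericVector pos, IntegerVector kcnt, NumericVector b,
                  int n, NumericVector grid, NumericVector alpha_grid) {
  const int S = pos.size(), G = grid.size(), A = alpha_grid.size();
  std::vector<double> b_full(n + 1, 0.0);
  for (int k = 1; k <= n - 1; ++k) b_full[k] = b[k - 1];
  auto q = escape_class_probs(b_full, n);
  // per-e polymorphism mass
  std::vector<double> poly(n + 1);
  for (int e = 0; e <= n; ++e) poly[e] = 1.0 - q[e][0] - q[e][n];
  const double LOG_FLOOR = -700.0;

  // null log-likelihood
  double ll0 = 0.0;
  std::vector<double> lb(n + 1, LOG_FLOOR);
  for (int k = 1; k <= n - 1; ++k)
    if (b_full[k] > 0) lb[k] = std::log(b_full[k]);
  for (int i = 0; i < S; ++i) ll0 += lb[kcnt[i]];

  // log pmf of Binomial(n, p) weights, computed by recurrence per (alpha, d)
  NumericVector stat(G), arg_alpha(G);
  std::vector<double> w(n + 1);
  const double AD_BACKGROUND = 36.0;  // exp(-36) ~ 2e-16: site is background

  for (int gI = 0; gI < G; ++gI) {
    double best = ll0;        // alpha = Inf member: exactly the null
    double best_alpha = R_PosInf;
    for (int aI = 0; aI < A; ++aI) {
      double alpha = alpha_grid[aI];
      double ll = 0.0;
      for (int i = 0; i < S; ++i) {
        double d = std::fabs(pos[i] - grid[gI]);
        double ad = alpha * d;
        if (ad > AD_BACKGROUND) { ll += lb[kcnt[i]]; continue; }
        double pe = -std::expm1(-ad);
        // binomial weights over the e-classes that carry mass
        int e_lo = 0, e_hi = n;
        if (pe <= 0.0) {
          e_hi = 0;
          w[0] = 1.0;
        } else if (pe >= 1.0) {
          e_lo = n;
          w[n] = 1.0;
        } else {
          double m0 = n * pe, sd0 = std::sqrt(n * pe * (1.0 - pe));
          e_lo = std::max(0, (int)std::floor(m0 - 8.0 * sd0 - 4.0));
          e_hi = std::min(n, (int)std::ceil(m0 + 8.0 * sd0 + 4.0));
          double ratio = pe / (1.0 - pe);
          w[e_lo] = R::dbinom((double)e_lo, (double)n, pe, 0);
          for (int e = e_lo + 1; e <= e_hi; ++e)
            w[e] = w[e - 1] * ratio * (double)(n - e + 1) / (double)e;
        }
        double num = 0.0, den = 0.0;
        int kk = kcnt[i];
        for (int e = e_lo; e <= e_hi; ++e) {
          num += w[e] * q[e][kk];
          den += w[e] * poly[e];
        }
        double lp = (num > 0 && den > 0) ? std::log(num / den) : LOG_FLOOR;
        ll += lp;
      }
      if (ll > best) { best = ll; best_alpha = alpha; }
    }
    stat[gI] = 2.0 * (best - ll0);
    arg_alpha[gI] = best_alpha;
  }
  return List::create(_["statistic"] = stat, _["arg_alpha"] = arg_alpha);
}

// Omega profile. r2: S x S matrix of squared allelic correlations; pos: site
// positions; grid: test positions; half_window: maximum physical distance of
// a used site from the test position; max_side: maximum number of sites kept
// on each side (nearest first); min_side: minimum sites per side (>= 2).
// Zero cross-block LD yields +Inf (reported as exceeding any threshold).
// Positions with too few sites get NA.
// [[Rcpp::export(name = ".cpp_omega_scan")]]
NumericVector cpp_omega_scan(NumericMatrix r2, NumericVector pos,
                             NumericVector grid, double half_window,
                             int max_side, int min_side) {
  const int S = pos.size(), G = grid.size();
  NumericVector out(G);
  std::vector<int> left, right;
  for (int gI = 0; gI < G; ++gI) {
    double X = grid[gI];
    left.clear(); right.clear();
    // nearest-first site indices on each side
    int first_right = (int)(std::lower_bound(pos.begin(), pos.end(), X) -
                            pos.begin());
    for (int i = first_right - 1; i >= 0 && X - pos[i] <= half_window; --i)
      if ((int)left.size() < max_side) left.push_back(i);
    for (int i = first_right; i < S && pos[i] - X <= half_window; ++i)
      if ((int)right.size() < max_side) right.push_back(i);
    int nl = (int)left.size(), nr = (int)right.size();
    if (nl < min_side || nr < min_side) { out[gI] = NA_REAL; continue; }
    // incremental sums over nearest-m prefixes
    std::vector<double> Lsum(nl + 1, 0.0), Rsum(nr + 1, 0.0);
    for (int i = 1; i < nl; ++i) {
      double add = 0.0;
      for (int j = 0; j < i; ++j) add += r2(left[i], left[j]);
      Lsum[i + 1] = Lsum[i] + add;
    }
    for (int i = 1; i < nr; ++i) {
      double add = 0.0;
      for (int j = 0; j < i; ++j) add += r2(right[i], right[j]);
      Rsum[i + 1] = Rsum[i] + add;
    }
    // cross sums X[i][j] for i left sites, j right sites
    std::vector<std::vector<double>> cross(
        nl + 1, std::vector<double>(nr + 1, 0.0));
    for (int i = 1; i <= nl; ++i) {
      double run = 0.0;
      for (int j = 1; j <= nr; ++j) {
        run += r2(left[i - 1], right[j - 1]);
        cross[i][j] = cross[i - 1][j] + run;
      }
    }
    double best = NA_REAL;
    for (int i = min_side; i <= nl; ++i) {
      for (int j = min_side; j <= nr; ++j) {
        double within = Lsum[i] + Rsum[j];
        double npairs_within = 0.5 * i * (i - 1.0) + 0.5 * j * (j - 1.0);
        double across = cross[i][j];
        double om;
        if (across <= 0.0) {
          om = (within > 0.0) ? R_PosInf : NA_REAL;
        } else {
          om = (within / npairs_within) / (across / ((double)i * j));
        }
        if (!ISNA(om) && (ISNA(best) || om > best)) best = om;
      }
    }
    out[gI] = best;
  }
  return out;
}
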