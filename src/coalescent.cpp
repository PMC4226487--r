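// Backward-in-time coalescent with recombination under piecewise-constant
// demography, plus a structured (two-background) phase tracing lineages
// through a conditioned beneficial-allele frequency trajectory.
//
// Conventions: time in generations before sampling; population sizes as
// chromosome counts (2N); positions in base pairs on [0, L). Sample size
// n <= 128 (two 64-bit descendant words per ancestral segment).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Bits {
  uint64_t w0, w1;
  Bits() : w0(0), w1(0) {}
  Bits(uint64_t a, uint64_t b) : w0(a), w1(b) {}
};

inline Bits bor(const Bits& a, const Bits& b) {
  return Bits(a.w0 | b.w0, a.w1 | b.w1);
}
inline bool beq(const Bits& a, const Bits& b) {
  return a.w0 == b.w0 && a.w1 == b.w1;
}

struct Seg {
  double a, b;  // [a, b)
  Bits bits;
};

enum { BG_WILD = 0, BG_BEN = 1 };

struct Lin {
  std::vector<Seg> segs;  // sorted, disjoint
  int bg;
  double anc_len;

  double span_a() const { return segs.front().a; }
  double span_b() const { return segs.back().b; }
  double span_len() const { return span_b() - span_a(); }
  void recompute() {
    anc_len = 0.0;
    for (const Seg& s : segs) anc_len += s.b - s.a;
  }
};

struct Site {
  double pos;
  Bits bits;
};

struct Sim {
  int n;
  double L, mu, rr;
  Bits full;
  std::vector<Lin> lin;
  std::vector<Site> sites;

  static void push_seg(std::vector<Seg>& v, double a, double b, const Bits& x) {
    if (b <= a) return;
    if (!v.empty() && v.back().b == a && beq(v.back().bits, x)) {
      v.back().b = b;  // merge contiguous identical segments
    } else {
      v.push_back(Seg{a, b, x});
    }
  }

  // Merge lineage j into lineage i (survivor keeps index i; j is erased;
  // if everything reaches the full sample both are erased).
  // Returns the number of lineages removed (1 or 2).
  int coalesce(int i, int j) {
    std::vector<Seg> out;
    out.reserve(lin[i].segs.size() + lin[j].segs.size());
    size_t ia = 0, ib = 0;
    const std::vector<Seg>& A = lin[i].segs;
    const std::vector<Seg>& B = lin[j].segs;
    Seg ca{}, cb{};
    bool hava = false, havb = false;
    while (true) {
      if (!hava && ia < A.size()) { ca = A[ia++]; hava = true; }
      if (!havb && ib < B.size()) { cb = B[ib++]; havb = true; }
      if (!hava && !havb) break;
      if (hava && (!havb || ca.b <= cb.a)) {
        push_seg(out, ca.a, ca.b, ca.bits);
        hava = false;
        continue;
      }
      if (havb && (!hava || cb.b <= ca.a)) {
        push_seg(out, cb.a, cb.b, cb.bits);
        havb = false;
        continue;
      }
      // overlapping heads
      double os = std::max(ca.a, cb.a);
      if (ca.a < os) push_seg(out, ca.a, os, ca.bits);
      if (cb.a < os) push_seg(out, cb.a, os, cb.bits);
      double oe = std::min(ca.b, cb.b);
      Bits u = bor(ca.bits, cb.bits);
      if (!beq(u, full)) push_seg(out, os, oe, u);  // full => local MRCA
      if (ca.b > oe) ca.a = oe; else hava = false;
      if (cb.b > oe) cb.a = oe; else havb = false;
    }
    if (out.empty()) {
      int hi = std::max(i, j), lo = std::min(i, j);
      lin.erase(lin.begin() + hi);
      lin.erase(lin.begin() + lo);
      return 2;
    }
    lin[i].segs = std::move(out);
    lin[i].recompute();
    lin.erase(lin.begin() + j);
    return 1;
  }

  // Split lineage i at crossover point u strictly inside its span.
  // Returns the index of the new right-hand lineage, or -1.
  int split(int i, double u) {
    Lin& p = lin[i];
    if (u <= p.span_a() || u >= p.span_b()) return -1;
    std::vector<Seg> left, right;
    for (const Seg& s : p.segs) {
      if (s.b <= u) left.push_back(s);
      else if (s.a >= u) right.push_back(s);
      else {
        left.push_back(Seg{s.a, u, s.bits});
        right.push_back(Seg{u, s.b, s.bits});
      }
    }
    if (left.empty() || right.empty()) return -1;
    Lin q;
    q.segs = std::move(right);
    q.bg = p.bg;
    q.recompute();
    p.segs = std::move(left);
    p.recompute();
    lin.push_back(std::move(q));
    return (int)lin.size() - 1;
  }

  double total_anc() const {
    double s = 0.0;
    for (const Lin& l : lin) s += l.anc_len;
    return s;
  }
  double total_span() const {
    double s = 0.0;
    for (const Lin& l : lin) s += l.span_len();
    return s;
  }

  void add_mutation() {
    double tot = total_anc();
    if (tot <= 0) return;
    double target = unif_rand() * tot;
    double acc = 0.0;
    int i = (int)lin.size() - 1;
    for (size_t q = 0; q < lin.size(); ++q) {
      acc += lin[q].anc_len;
      if (target <= acc) { i = (int)q; break; }
    }
    double u = unif_rand() * lin[i].anc_len;
    acc = 0.0;
    for (const Seg& s : lin[i].segs) {
      acc += s.b - s.a;
      if (u <= acc) {
        sites.push_back(Site{s.b - (acc - u), s.bits});
        return;
      }
    }
  }

  void mutate_interval(double dt) {
    double tot = total_anc();
    if (tot <= 0 || dt <= 0) return;
    int m = (int)R::rpois(mu * tot * dt);
    for (int k = 0; k < m; ++k) add_mutation();
  }
};

// Wright-Fisher parent assignment for one background class: each member of
// `cls` (lineage indices) draws a parent among M chromosomes; members sharing
// a parent coalesce. Multi-merger safe, which matters for bottleneck
// populations of a handful of chromosomes. `other` is kept index-consistent.
void wf_merge_class(Sim& sim, std::vector<int>& cls, int M,
                    std::vector<int>& other) {
  if ((int)cls.size() < 2 || M < 1) return;
  std::vector<int> parent(cls.size());
  for (size_t i = 0; i < cls.size(); ++i)
    parent[i] = (int)std::floor(unif_rand() * M);
  for (size_t i = 0; i < cls.size(); ++i) {
    if (cls[i] < 0) continue;
    for (size_t g = i + 1; g < cls.size(); ++g) {
      if (cls[g] < 0 || parent[g] != parent[i]) continue;
      int a = cls[i], b = cls[g];
      int lo = std::min(a, b), hi = std::max(a, b);
      int removed = sim.coalesce(lo, hi);
      auto remap = [&](int& v) {
        if (v < 0) return;
        if (removed == 2) {
          if (v == lo || v == hi) { v = -1; return; }
          v -= (v > lo ? 1 : 0) + (v > hi ? 1 : 0);
        } else {
          if (v == hi) { v = lo; return; }
          if (v > hi) v -= 1;
        }
      };
      for (int& v : cls) remap(v);
      for (int& v : other) remap(v);
      if (removed == 1) cls[g] = -1;  // merged into cls[i]
      if (cls[i] < 0) break;          // both pieces hit local MRCA
    }
  }
  cls.erase(std::remove_if(cls.begin(), cls.end(),
                           [](int v) { return v < 0; }),
            cls.end());
  other.erase(std::remove_if(other.begin(), other.end(),
                             [](int v) { return v < 0; }),
              other.end());
}

}  // namespace

// Conditioned Wright-Fisher frequency path: forward simulation from one copy
// with selection, rejection-sampled until fixation, returned backward in time
// (element 0 = frequency one generation before fixation; last element =
// 1/N2b, the origin). N2b = bottleneck chromosome count.
// [[Rcpp::export(name = ".cpp_trajectory_wf")]]
NumericVector cpp_trajectory_wf(int N2b, double s, int max_tries = 1000000) {
  if (N2b < 2)
    stop("bottleneck population has fewer than one diploid individual (N_b < 1)");
  std::vector<double> path;
  for (int tries = 0; tries < max_tries; ++tries) {
    path.clear();
    int j = 1;
    path.push_back(1.0 / N2b);
    bool fixed = false;
    while (true) {
      double x = (double)j / N2b;
      double p = x * (1.0 + s) / (x * (1.0 + s) + (1.0 - x));
      j = (int)R::rbinom((double)N2b, p);
      if (j == 0) break;
      if (j == N2b) { fixed = true; break; }
      path.push_back((double)j / N2b);
    }
    if (fixed) {
      std::reverse(path.begin(), path.end());
      return NumericVector(path.begin(), path.end());
    }
  }
  stop("trajectory rejection sampling failed to fix; raise s or the bottleneck size");
}

// Deterministic logistic path for strong selection, sampled once per
// generation, backward in time as above.
// [[Rcpp::export(name = ".cpp_trajectory_logistic")]]
NumericVector cpp_trajectory_logistic(int N2b, double s) {
  if (N2b < 2)
    stop("bottleneck population has fewer than one diploid individual (N_b < 1)");
  std::vector<double> fwd;
  double x = 1.0 / N2b;
  fwd.push_back(x);
  while (x < 1.0 - 1.0 / N2b) {
    double lg = std::log(x / (1.0 - x)) + s;  // dx/dt = s x (1 - x)
    x = 1.0 / (1.0 + std::exp(-lg));
    fwd.push_back(x);
    if (fwd.size() > 100000000u) stop("logistic trajectory did not fix");
  }
  std::reverse(fwd.begin(), fwd.end());
  return NumericVector(fwd.begin(), fwd.end());
}

// Core simulator.
//
// epoch_end: generation at which each epoch ends (increasing; last = Inf);
// epoch_N2: chromosome count 2N within each epoch.
// traj: backward-in-time beneficial-allele frequencies, one per generation,
// starting at tau_g (length 0 = neutral run). N2b: bottleneck chromosome
// count defining the sweep-phase subpopulation sizes.
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(int n, double L, double mu, double rr,
                  NumericVector epoch_end, NumericVector epoch_N2,
                  double tau_g, NumericVector traj, double x_sel, int N2b) {
  if (n < 2 || n > 128) stop("sample size must be between 2 and 128 chromosomes");
  Sim sim;
  sim.n = n;
  sim.L = L;
  sim.mu = mu;
  sim.rr = rr;
  sim.full = Bits(
      n >= 64 ? ~0ULL : ((1ULL << n) - 1),
      n <= 64 ? 0ULL : (n >= 128 ? ~0ULL : ((1ULL << (n - 64)) - 1)));
  sim.lin.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    Lin l;
    Bits b;
    if (i < 64) b.w0 = 1ULL << i; else b.w1 = 1ULL << (i - 64);
    l.segs.push_back(Seg{0.0, L, b});
    l.bg = BG_WILD;
    l.recompute();
    sim.lin.push_back(std::move(l));
  }

  const bool has_sweep = traj.size() > 0;
  const double sweep_start = has_sweep ? tau_g : R_PosInf;
  const double sweep_end = has_sweep ? tau_g + traj.size() : R_PosInf;
  bool sweep_entered = false;
  const double WF_N2_THRESHOLD = 50.0;  // per-generation stepping below this

  double t = 0.0;
  int ep = 0;
  long guard = 0;
  const long GUARD_MAX = 400000000L;

  while (!sim.lin.empty()) {
    if (++guard > GUARD_MAX) stop("simulation exceeded its event budget");
    while (ep < epoch_end.size() - 1 && t >= epoch_end[ep]) ++ep;
    double N2 = epoch_N2[ep];
    double stretch_end = epoch_end[ep];
    if (t < sweep_start) stretch_end = std::min(stretch_end, sweep_start);

    if (has_sweep && !(t < sweep_start) && t < sweep_end) {
      // ---- structured sweep phase: per-generation stepping ----
      if (!sweep_entered) {
        for (Lin& l : sim.lin) l.bg = BG_BEN;
        sweep_entered = true;
      }
      int g = (int)std::floor(t - sweep_start);
      if (g < 0) g = 0;
      for (; g < traj.size() && !sim.lin.empty(); ++g) {
        if (++guard > GUARD_MAX) stop("simulation exceeded its event budget");
        double x = traj[g];
        int MB = std::max(1, (int)std::lround((double)N2b * x));
        int Mb = std::max(1, (int)std::lround((double)N2b * (1.0 - x)));
        // recombination over the span stretched to the selected site
        size_t nl = sim.lin.size();
        for (size_t i = 0; i < nl; ++i) {
          double sa = std::min(sim.lin[i].span_a(), x_sel);
          double sb = std::max(sim.lin[i].span_b(), x_sel);
          int nev = (int)R::rpois(rr * (sb - sa));
          for (int e = 0; e < nev; ++e) {
            double u = sa + unif_rand() * (sb - sa);
            double ma = sim.lin[i].span_a(), mb = sim.lin[i].span_b();
            if (u > ma && u < mb) {
              int j = sim.split((int)i, u);
              if (j >= 0) {
                // the piece on the selected-site side keeps the background;
                // the far piece lands on a chromosome drawn from the
                // current beneficial-allele frequency
                int far = (x_sel <= u) ? j : (int)i;
                sim.lin[far].bg = (unif_rand() < x) ? BG_BEN : BG_WILD;
              }
            } else {
              // crossover between the material and the selected site:
              // the whole material block moves to a random chromosome
              bool cut = (x_sel < ma && u > x_sel && u < ma) ||
                         (x_sel >= mb && u >= mb && u < x_sel);
              if (cut)
                sim.lin[i].bg = (unif_rand() < x) ? BG_BEN : BG_WILD;
            }
          }
        }
        // coalescence by WF parent assignment within each background
        std::vector<int> clsB, clsb;
        for (size_t i = 0; i < sim.lin.size(); ++i)
          (sim.lin[i].bg == BG_BEN ? clsB : clsb).push_back((int)i);
        wf_merge_class(sim, clsB, MB, clsb);
        wf_merge_class(sim, clsb, Mb, clsB);
        sim.mutate_interval(1.0);
        t += 1.0;
      }
      if (!sim.lin.empty() && g >= traj.size()) {
        // origin: every remaining beneficial-background lineage descends
        // from the single originating chromosome
        t = sweep_end;
        while (true) {
          int a = -1, b = -1;
          for (size_t i = 0; i < sim.lin.size(); ++i) {
            if (sim.lin[i].bg != BG_BEN) continue;
            if (a < 0) a = (int)i; else { b = (int)i; break; }
          }
          if (b < 0) break;
          sim.coalesce(a, b);
        }
        for (Lin& l : sim.lin) l.bg = BG_WILD;
      }
      continue;
    }

    if (N2 < WF_N2_THRESHOLD) {
      // ---- tiny population: discrete Wright-Fisher generations ----
      while (!sim.lin.empty() && t < stretch_end) {
        if (++guard > GUARD_MAX) stop("simulation exceeded its event budget");
        size_t nl = sim.lin.size();
        for (size_t i = 0; i < nl; ++i) {
          int nev = (int)R::rpois(rr * sim.lin[i].span_len());
          for (int e = 0; e < nev; ++e) {
            double u = sim.lin[i].span_a() +
                       unif_rand() * sim.lin[i].span_len();
            sim.split((int)i, u);
          }
        }
        std::vector<int> all, none;
        for (size_t i = 0; i < sim.lin.size(); ++i) all.push_back((int)i);
        wf_merge_class(sim, all, std::max(1, (int)std::lround(N2)), none);
        sim.mutate_interval(1.0);
        t += 1.0;
      }
      continue;
    }

    // ---- continuous-time phase ----
    int k = (int)sim.lin.size();
    double lam_c = 0.5 * k * (k - 1.0) / N2;  // pair rate 1/(2N) per gen
    double sum_span = sim.total_span();
    double sum_anc = sim.total_anc();
    double lam = lam_c + rr * sum_span + mu * sum_anc;
    double dt = R::exp_rand() / lam;
    if (t + dt >= stretch_end) {
      if (!R_finite(stretch_end))
        stop("internal error: infinite epoch with zero progress");
      t = stretch_end;
      continue;
    }
    t += dt;
    double u = unif_rand() * lam;
    if (u < lam_c) {
      int i = (int)std::floor(unif_rand() * k);
      int j = (int)std::floor(unif_rand() * (k - 1));
      if (j >= i) ++j;
      sim.coalesce(std::min(i, j), std::max(i, j));
    } else if (u < lam_c + rr * sum_span) {
      double target = unif_rand() * sum_span;
      double acc = 0.0;
      int i = k - 1;
      for (int q = 0; q < k; ++q) {
        acc += sim.lin[q].span_len();
        if (target <= acc) { i = q; break; }
      }
      double pos = sim.lin[i].span_a() + unif_rand() * sim.lin[i].span_len();
      sim.split(i, pos);
    } else {
      sim.add_mutation();
    }
  }

  std::sort(sim.sites.begin(), sim.sites.end(),
            [](const Site& a, const Site& b) { return a.pos < b.pos; });
  for (size_t i = 1; i < sim.sites.size(); ++i)
    if (sim.sites[i].pos <= sim.sites[i - 1].pos)
      sim.sites[i].pos = std::nextafter(sim.sites[i - 1].pos, R_PosInf);
  int S = (int)sim.sites.size();
  IntegerMatrix m(n, S);
  NumericVector pos(S);
  for (int sI = 0; sI < S; ++sI) {
    pos[sI] = sim.sites[sI].pos;
    const Bits& b = sim.sites[sI].bits;
    for (int i = 0; i < n; ++i) {
      bool set = (i < 64) ? ((b.w0 >> i) & 1ULL)
                          : ((b.w1 >> (i - 64)) & 1ULL);
      m(i, sI) = set ? 1 : 0;
    }
  }
  return List::create(_["positions"] = pos, _["alleles"] = m);
}
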