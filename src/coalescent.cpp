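#include "demog.h"
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Structured coalescent with recombination, conditional on a derived-allele
// copy-number trajectory.  Sampled lineages start in the derived (focal
// allele carrying) or ancestral allelic class; backward in time, lineages in
// a class pick parents among the class copies (derived class: trajectory
// count c_t; ancestral class: 2N_t - c_t), so coalescence -- including
// simultaneous multiple mergers when class sizes are small -- follows the
// discrete Wright-Fisher genealogy.  Recombination splits a lineage at a
// uniform point of its ancestral-material span; the piece not containing the
// focal site joins the derived class with probability x_t = c_t / 2N_t.  At
// the origin generation (count 1) the last derived lineage transfers to the
// ancestral class and the process continues as a standard coalescent under
// the demography.  Infinite-sites mutations drop on all branches at rate u
// per bp per generation; sample-descent sets are tracked per segment as
// 128-bit masks and MRCA-complete material is pruned.
//
// Generations with slowly varying event rates are traversed by geometric
// jumps; dense regimes (many lineages relative to class size) step one
// generation at a time with explicit parent assignment.
// ---------------------------------------------------------------------------

struct Mask { uint64_t a, b; };
static inline Mask mor(Mask x, Mask y) { return Mask{x.a | y.a, x.b | y.b}; }
static inline Mask mand(Mask x, Mask y) { return Mask{x.a & y.a, x.b & y.b}; }
static inline Mask mandnot(Mask x, Mask y) { return Mask{x.a & ~y.a, x.b & ~y.b}; }
static inline bool mnone(Mask x) { return x.a == 0 && x.b == 0; }
static inline bool meq(Mask x, Mask y) { return x.a == y.a && x.b == y.b; }
static inline int mcount(Mask x) {
  return __builtin_popcountll(x.a) + __builtin_popcountll(x.b);
}
static inline Mask mbit(int i) {
  return (i < 64) ? Mask{1ull << i, 0} : Mask{0, 1ull << (i - 64)};
}
static inline bool mhas(Mask x, int i) {
  return (i < 64) ? ((x.a >> i) & 1ull) : ((x.b >> (i - 64)) & 1ull);
}
static inline Mask mfull(int n) {
  Mask m{0, 0};
  if (n >= 64) { m.a = ~0ull; m.b = (n == 128) ? ~0ull : ((1ull << (n - 64)) - 1); }
  else m.a = (n == 64) ? ~0ull : ((1ull << n) - 1);
  return m;
}

struct Seg { double lo, hi; Mask m; };
struct Mut { double pos; Mask m; };

struct Lin {
  int cls;                 // 0 = derived, 1 = ancestral
  double t0;               // time the current segment set came into being
  double len;              // total ancestral-material length
  std::vector<Seg> segs;   // disjoint, sorted by position
  double span() const {
    return segs.empty() ? 0.0 : segs.back().hi - segs.front().lo;
  }
  void relen() {
    len = 0.0;
    for (size_t i = 0; i < segs.size(); ++i) len += segs[i].hi - segs[i].lo;
  }
};

struct Sim {
  std::vector<int> cbp;    // derived count at t generations before present
  NumericVector sizes_bp, ends_bp;
  double u, r, L, focal, max_time;
  int n_d, n_total;
  Mask full;
  std::vector<Lin> lins;
  std::vector<Mut> muts;
  // pair mode (n_total == 2): once the pair differs at a position, material
  // beyond that position (relative to the focal site) cannot change the
  // first-difference distance and is pruned
  bool pair_mode;
  bool prune_dirty;
  double keep_lo, keep_hi;
};

static void flush_muts(Sim& S, Lin& ln, double t) {
  if (ln.len <= 0.0 || t <= ln.t0) { ln.t0 = t; return; }
  double lam = S.u * ln.len * (t - ln.t0);
  int nm = (lam > 0.0) ? (int) R::rpois(lam) : 0;
  for (int i = 0; i < nm; ++i) {
    double x = R::unif_rand() * ln.len;
    double acc = 0.0;
    for (size_t k = 0; k < ln.segs.size(); ++k) {
      double w = ln.segs[k].hi - ln.segs[k].lo;
      if (x < acc + w) {
        double pos = ln.segs[k].lo + (x - acc);
        S.muts.push_back(Mut{pos, ln.segs[k].m});
        if (S.pair_mode) {
          if (pos > S.focal && pos < S.keep_hi) {
            S.keep_hi = pos;
            S.prune_dirty = true;
          } else if (pos < S.focal && pos > S.keep_lo) {
            S.keep_lo = pos;
            S.prune_dirty = true;
          }
        }
        break;
      }
      acc += w;
    }
  }
  ln.t0 = t;
}

// truncate all lineages to the still-relevant interval [keep_lo, keep_hi]
static void prune_all(Sim& S, double t) {
  if (!S.prune_dirty) return;
  S.prune_dirty = false;
  size_t i = 0;
  while (i < S.lins.size()) {
    Lin& ln = S.lins[i];
    flush_muts(S, ln, t);
    std::vector<Seg> kept;
    for (size_t k = 0; k < ln.segs.size(); ++k) {
      Seg sg = ln.segs[k];
      if (sg.hi <= S.keep_lo || sg.lo >= S.keep_hi) continue;
      if (sg.lo < S.keep_lo) sg.lo = S.keep_lo;
      if (sg.hi > S.keep_hi) sg.hi = S.keep_hi;
      if (sg.hi > sg.lo) kept.push_back(sg);
    }
    ln.segs.swap(kept);
    ln.relen();
    if (ln.segs.empty()) {
      S.lins.erase(S.lins.begin() + i);
    } else {
      ++i;
    }
  }
}

// union of two disjoint-sorted segment lists, dropping MRCA-complete pieces
static std::vector<Seg> merge_segs(const std::vector<Seg>& A,
                                   const std::vector<Seg>& B, Mask full) {
  std::vector<double> pts;
  pts.reserve(2 * (A.size() + B.size()));
  for (size_t i = 0; i < A.size(); ++i) { pts.push_back(A[i].lo); pts.push_back(A[i].hi); }
  for (size_t i = 0; i < B.size(); ++i) { pts.push_back(B[i].lo); pts.push_back(B[i].hi); }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  std::vector<Seg> C;
  size_t ia = 0, ib = 0;
  for (size_t i = 0; i + 1 < pts.size(); ++i) {
    double lo = pts[i], hi = pts[i + 1];
    double mid = 0.5 * (lo + hi);
    Mask m{0, 0};
    while (ia < A.size() && A[ia].hi <= lo) ++ia;
    if (ia < A.size() && A[ia].lo <= mid && mid < A[ia].hi) m = mor(m, A[ia].m);
    while (ib < B.size() && B[ib].hi <= lo) ++ib;
    if (ib < B.size() && B[ib].lo <= mid && mid < B[ib].hi) m = mor(m, B[ib].m);
    if (mnone(m) || meq(m, full)) continue;
    if (!C.empty() && C.back().hi == lo && meq(C.back().m, m)) C.back().hi = hi;
    else C.push_back(Seg{lo, hi, m});
  }
  return C;
}

// coalesce by indices, leaving S.lins rebuilt without invalid entries
static void coalesce_pair(Sim& S, size_t i, size_t j, double t) {
  flush_muts(S, S.lins[i], t);
  flush_muts(S, S.lins[j], t);
  std::vector<Seg> merged = merge_segs(S.lins[i].segs, S.lins[j].segs, S.full);
  if (j < i) std::swap(i, j);
  if (merged.empty()) {
    S.lins.erase(S.lins.begin() + j);
    S.lins.erase(S.lins.begin() + i);
  } else {
    S.lins[i].segs = merged;
    S.lins[i].relen();
    S.lins[i].t0 = t;
    S.lins.erase(S.lins.begin() + j);
  }
}

// one generation of within-class parent assignment (handles multiple and
// simultaneous mergers); pool = number of parental copies of that class
static void class_parents(Sim& S, int cls, int pool, double t_par) {
  std::vector<size_t> idx;
  for (size_t i = 0; i < S.lins.size(); ++i)
    if (S.lins[i].cls == cls) idx.push_back(i);
  if (idx.size() < 2) return;
  if (pool < 1) pool = 1;
  std::vector<int> parent(idx.size());
  for (size_t i = 0; i < idx.size(); ++i)
    parent[i] = (int) std::floor(R::unif_rand() * pool);
  std::vector<char> grouped(idx.size(), 0);
  std::vector<char> drop(S.lins.size(), 0);
  std::vector<Lin> born;
  for (size_t i = 0; i < idx.size(); ++i) {
    if (grouped[i]) continue;
    std::vector<size_t> grp(1, idx[i]);
    for (size_t j = i + 1; j < idx.size(); ++j)
      if (!grouped[j] && parent[j] == parent[i]) {
        grp.push_back(idx[j]);
        grouped[j] = 1;
      }
    if (grp.size() < 2) continue;
    for (size_t g = 0; g < grp.size(); ++g) {
      flush_muts(S, S.lins[grp[g]], t_par);
      drop[grp[g]] = 1;
    }
    std::vector<Seg> segs = S.lins[grp[0]].segs;
    for (size_t g = 1; g < grp.size(); ++g)
      segs = merge_segs(segs, S.lins[grp[g]].segs, S.full);
    if (!segs.empty()) {
      Lin ln;
      ln.cls = cls;
      ln.t0 = t_par;
      ln.segs = segs;
      ln.relen();
      born.push_back(ln);
    }
  }
  std::vector<Lin> keep;
  keep.reserve(S.lins.size());
  for (size_t i = 0; i < S.lins.size(); ++i)
    if (!drop[i]) keep.push_back(S.lins[i]);
  for (size_t i = 0; i < born.size(); ++i) keep.push_back(born[i]);
  S.lins.swap(keep);
}

// split lineage i at a uniform breakpoint of its span; the piece without the
// focal site joins the derived class with probability x
static void recombine(Sim& S, size_t i, double t, double x) {
  Lin& ln = S.lins[i];
  if (ln.segs.empty() || ln.span() <= 0.0) return;
  flush_muts(S, ln, t);
  double bp = ln.segs.front().lo + R::unif_rand() * ln.span();
  std::vector<Seg> left, right;
  for (size_t k = 0; k < ln.segs.size(); ++k) {
    const Seg& sg = ln.segs[k];
    if (sg.hi <= bp) left.push_back(sg);
    else if (sg.lo >= bp) right.push_back(sg);
    else {
      left.push_back(Seg{sg.lo, bp, sg.m});
      right.push_back(Seg{bp, sg.hi, sg.m});
    }
  }
  if (left.empty() || right.empty()) return;  // breakpoint at material edge
  bool focal_right = (S.focal >= bp);
  Lin other;
  other.t0 = t;
  other.cls = (R::unif_rand() < x) ? 0 : 1;
  if (focal_right) { ln.segs = right; other.segs = left; }
  else             { ln.segs = left;  other.segs = right; }
  ln.relen();
  ln.t0 = t;
  other.relen();
  S.lins.push_back(other);
}

static void per_lineage_recomb(Sim& S, double t, double x) {
  size_t nl = S.lins.size();  // pieces born this generation do not recombine
  for (size_t i = 0; i < nl; ++i) {
    double pr = S.r * S.lins[i].span();
    if (pr > 0.0 && R::unif_rand() < pr) recombine(S, i, t, x);
  }
}

static inline double tot_span(const Sim& S) {
  double sp = 0.0;
  for (size_t i = 0; i < S.lins.size(); ++i) sp += S.lins[i].span();
  return sp;
}

static void pick_random_pair_of_class(Sim& S, int cls, int k, size_t& ia, size_t& ib) {
  int a = (int) std::floor(R::unif_rand() * k);
  int b = (int) std::floor(R::unif_rand() * (k - 1));
  if (b >= a) ++b;
  int cnt = 0;
  ia = ib = 0;
  for (size_t i = 0; i < S.lins.size(); ++i)
    if (S.lins[i].cls == cls) {
      if (cnt == a) ia = i;
      if (cnt == b) ib = i;
      ++cnt;
    }
}

static void run_sim(Sim& S, int n_anc_samp) {
  const int age = S.cbp.size();
  S.muts.clear();
  S.lins.clear();
  S.keep_lo = 0.0;
  S.keep_hi = S.L;
  S.prune_dirty = false;

  for (int i = 0; i < S.n_d + n_anc_samp; ++i) {
    Lin ln;
    ln.cls = (i < S.n_d) ? 0 : 1;
    ln.t0 = 0.0;
    ln.segs.push_back(Seg{0.0, S.L, mbit(i)});
    ln.relen();
    S.lins.push_back(ln);
  }
  // sampled chromosomes pick present-day population copies with replacement
  // (the binomial-sampling convention); shared copies merge immediately
  class_parents(S, 0, S.cbp[0], 0.0);

  double t = 0.0;
  // ----- phase A: derived class present (until the origin generation) -----
  // Hazard accumulation: between events the per-generation event
  // probabilities depend only on the trajectory count, so generations are
  // scanned arithmetically and one Exp(1) draw decides the next event time.
  {
    int k_d = 0, k_a = 0;
    for (size_t i = 0; i < S.lins.size(); ++i)
      (S.lins[i].cls == 0 ? ++k_d : ++k_a);
    double sp = tot_span(S);
    double eneed = R::exp_rand();
    double cum = 0.0;
    while (t < age - 1 && !S.lins.empty()) {
      if (k_d == 0 && k_a <= 1) break;
      double tp = t + 1.0;
      double twoN = 2.0 * size_bp(tp, S.sizes_bp, S.ends_bp);
      int c = S.cbp[(int) tp];
      double p_dc = (k_d >= 2) ? k_d * (k_d - 1.0) / 2.0 / c : 0.0;
      if (p_dc > 0.3) {
        // dense derived class: explicit multi-merger parent assignment
        class_parents(S, 0, c, tp);
        per_lineage_recomb(S, tp, c / twoN);
        prune_all(S, tp);
        k_d = k_a = 0;
        for (size_t i = 0; i < S.lins.size(); ++i)
          (S.lins[i].cls == 0 ? ++k_d : ++k_a);
        sp = tot_span(S);
        eneed = R::exp_rand();
        cum = 0.0;
        t = tp;
        continue;
      }
      double p_ac = (k_a >= 2) ?
        k_a * (k_a - 1.0) / 2.0 / std::max(1.0, twoN - c) : 0.0;
      double p_r = S.r * sp;
      double ptot = p_dc + p_ac + p_r;
      if (ptot <= 0.0) { t = tp; continue; }
      double h = -std::log1p(-std::min(0.95, ptot));
      if (cum + h < eneed) { cum += h; t = tp; continue; }
      // event this generation
      t = tp;
      double u = R::unif_rand() * ptot;
      if (u < p_dc) {
        size_t ia, ib;
        pick_random_pair_of_class(S, 0, k_d, ia, ib);
        coalesce_pair(S, ia, ib, t);
      } else if (u < p_dc + p_ac) {
        size_t ia, ib;
        pick_random_pair_of_class(S, 1, k_a, ia, ib);
        coalesce_pair(S, ia, ib, t);
      } else {
        size_t idx = 0;
        double xx = R::unif_rand() * sp, acc = 0.0;
        for (size_t i = 0; i < S.lins.size(); ++i) {
          acc += S.lins[i].span();
          if (xx < acc) { idx = i; break; }
        }
        recombine(S, idx, t, c / twoN);
      }
      prune_all(S, t);
      k_d = k_a = 0;
      for (size_t i = 0; i < S.lins.size(); ++i)
        (S.lins[i].cls == 0 ? ++k_d : ++k_a);
      sp = tot_span(S);
      eneed = R::exp_rand();
      cum = 0.0;
      if (t > S.max_time) break;
    }
  }

  // origin: remaining derived lineages coalesce into one and transfer to the
  // ancestral class (the focal mutation arose on a single copy)
  if (t < age - 1) t = age - 1;
  {
    class_parents(S, 0, 1, (double) (age - 1));
    for (size_t i = 0; i < S.lins.size(); ++i) S.lins[i].cls = 1;
  }

  // ----- phase B: standard coalescent under the demography -----
  while (S.lins.size() > 1 && t < S.max_time) {
    prune_all(S, t);
    if (S.lins.size() <= 1) break;
    int k = S.lins.size();
    double twoN = 2.0 * size_bp(t + 1.0, S.sizes_bp, S.ends_bp);
    double pc = k * (k - 1.0) / 2.0 / twoN;
    double sp = tot_span(S);
    double pr = S.r * sp;
    if (pc > 0.3 || pc + pr > 0.5) {
      double tp = t + 1.0;
      class_parents(S, 1, (int) twoN, tp);
      per_lineage_recomb(S, tp, 0.0);
      t = tp;
      continue;
    }
    double p = pc + pr;
    if (p <= 0.0) break;
    double cap = R_PosInf;
    for (int e = 0; e < S.ends_bp.size(); ++e)
      if (S.ends_bp[e] > t + 1e-9) { cap = S.ends_bp[e] - t; break; }
    double d = R::rgeom(p) + 1.0;
    if (d > cap) { t += cap; continue; }
    t += d;
    if (R::unif_rand() < pc / p) {
      size_t ia, ib;
      pick_random_pair_of_class(S, 1, k, ia, ib);
      coalesce_pair(S, ia, ib, t);
    } else {
      size_t idx = 0;
      double xx = R::unif_rand() * sp, acc = 0.0;
      for (size_t i = 0; i < S.lins.size(); ++i) {
        acc += S.lins[i].span();
        if (xx < acc) { idx = i; break; }
      }
      recombine(S, idx, t, 0.0);
    }
  }
  // time cap reached with unresolved material: flush mutations so far
  for (size_t i = 0; i < S.lins.size(); ++i) flush_muts(S, S.lins[i], t);
}

// first-difference window counts by partition refinement over the derived
// sample; dir = +1 counts distances downstream of the focal site, -1 upstream
static void count_windows(const std::vector<Mut>& muts, int n_d, double focal,
                          int dir, const NumericVector& bnd, double* w, int M,
                          int* pair_windows /* may be NULL; length C(n_d,2) */) {
  Mask dfull = mfull(n_d);
  std::vector<std::pair<double, Mask> > sites;
  double lastb = bnd[M - 2];
  for (size_t i = 0; i < muts.size(); ++i) {
    double dist = dir > 0 ? (muts[i].pos - focal) : (focal - muts[i].pos);
    if (dist <= 0.0 || dist > lastb) continue;
    Mask m = mand(muts[i].m, dfull);
    if (mnone(m) || meq(m, dfull)) continue;
    sites.push_back(std::make_pair(dist, m));
  }
  std::sort(sites.begin(), sites.end(),
            [](const std::pair<double, Mask>& a, const std::pair<double, Mask>& b) {
              return a.first < b.first;
            });
  std::vector<Mask> cls;
  if (n_d >= 2) cls.push_back(dfull);
  for (size_t si = 0; si < sites.size() && !cls.empty(); ++si) {
    double dist = sites[si].first;
    int wj = M - 1;
    for (int j = 0; j < M - 1; ++j)
      if (dist <= bnd[j]) { wj = j; break; }
    std::vector<Mask> nxt;
    nxt.reserve(cls.size() + 2);
    bool any = false;
    for (size_t ci = 0; ci < cls.size(); ++ci) {
      Mask inter = mand(cls[ci], sites[si].second);
      if (mnone(inter) || meq(inter, cls[ci])) { nxt.push_back(cls[ci]); continue; }
      any = true;
      Mask diff = mandnot(cls[ci], sites[si].second);
      int n1 = mcount(inter), n0 = mcount(diff);
      w[wj] += (double) n1 * n0;
      if (pair_windows) {
        for (int a = 0; a < n_d; ++a) {
          if (!mhas(inter, a)) continue;
          for (int b = 0; b < n_d; ++b) {
            if (!mhas(diff, b)) continue;
            int i1 = std::min(a, b), i2 = std::max(a, b);
            int pidx = i1 * n_d - i1 * (i1 + 1) / 2 + (i2 - i1 - 1);
            pair_windows[pidx] = wj + 1;
          }
        }
      }
      if (n1 >= 2) nxt.push_back(inter);
      if (n0 >= 2) nxt.push_back(diff);
    }
    if (any) cls.swap(nxt);
  }
  // pairs never split within the windowed span fall in the final window
  double rem = 0.0;
  for (size_t ci = 0; ci < cls.size(); ++ci) {
    int nc = mcount(cls[ci]);
    rem += nc * (nc - 1.0) / 2.0;
  }
  w[M - 1] += rem;
}

static void setup_sim(Sim& S, IntegerVector counts, NumericVector sizes_bp,
                      NumericVector ends_bp, int n, double u, double r,
                      double L, double focal, double max_time, int n_total) {
  S.cbp.assign(counts.size(), 0);
  for (int i = 0; i < counts.size(); ++i)
    S.cbp[i] = counts[counts.size() - 1 - i];  // index by gens before present
  S.sizes_bp = sizes_bp;
  S.ends_bp = ends_bp;
  S.u = u; S.r = r; S.L = L; S.focal = focal;
  S.max_time = max_time;
  S.n_d = n;
  S.n_total = n_total;
  S.full = mfull(n_total);
  S.pair_mode = (n_total == 2);
  S.keep_lo = 0.0;
  S.keep_hi = L;
  S.prune_dirty = false;
}

// Pooled window counts over `reps` haplotype sets per trajectory, with the
// focal allele at the left end of a one-sided region (the table-building
// convention).  Returns a K x M matrix of counts.
// [[Rcpp::export]]
NumericMatrix cpp_window_counts_batch(List counts_list, NumericVector sizes_bp,
                                      NumericVector ends_bp, int n, double u,
                                      double r, NumericVector boundaries,
                                      int reps, double max_time) {
  const int K = counts_list.size();
  const int M = boundaries.size() + 1;
  const double span = boundaries[M - 2];
  NumericMatrix out(K, M);
  Sim S;
  for (int k = 0; k < K; ++k) {
    IntegerVector cc = counts_list[k];
    setup_sim(S, cc, sizes_bp, ends_bp, n, u, r, span, 0.0, max_time, n);
    std::vector<double> w(M, 0.0);
    for (int rep = 0; rep < reps; ++rep) {
      run_sim(S, 0);
      count_windows(S.muts, n, 0.0, +1, boundaries, w.data(), M, NULL);
    }
    for (int j = 0; j < M; ++j) out(k, j) = w[j];
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Per-pair window indices for data-style loci: focal allele at the midpoint
// when both directions are used, otherwise at the left end.  Returns, per
// locus, an integer matrix with C(n,2) rows (pair order (1,2),(1,3),...,
// (2,3),...) and `directions` columns (downstream first).
// [[Rcpp::export]]
List cpp_ibs_pair_windows(List counts_list, NumericVector sizes_bp,
                          NumericVector ends_bp, int n, double u, double r,
                          NumericVector boundaries, int directions,
                          double max_time) {
  const int A = counts_list.size();
  const int M = boundaries.size() + 1;
  const double span = boundaries[M - 2];
  const int npair = n * (n - 1) / 2;
  List out(A);
  Sim S;
  for (int a = 0; a < A; ++a) {
    IntegerVector cc = counts_list[a];
    double L = directions == 2 ? 2.0 * span : span;
    double focal = directions == 2 ? span : 0.0;
    setup_sim(S, cc, sizes_bp, ends_bp, n, u, r, L, focal, max_time, n);
    run_sim(S, 0);
    IntegerMatrix pw(npair, directions);
    std::vector<double> w(M, 0.0);
    for (int d = 0; d < directions; ++d) {
      int* colp = &pw(0, d);
      for (int q = 0; q < npair; ++q) colp[q] = M;
      count_windows(S.muts, n, focal, d == 0 ? +1 : -1, boundaries, w.data(),
                    M, colp);
    }
    out[a] = pw;
    if (a % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full haplotype output: positions of segregating sites in [0, region_l] and
// a 0/1 matrix with one row per sampled haplotype (derived samples first).
// The focal site itself is not included.
// [[Rcpp::export]]
List cpp_simulate_haplotypes(IntegerVector counts, NumericVector sizes_bp,
                             NumericVector ends_bp, int n_derived,
                             int n_ancestral, double u, double r,
                             double region_l, double focal_pos,
                             double max_time) {
  Sim S;
  setup_sim(S, counts, sizes_bp, ends_bp, n_derived, u, r, region_l, focal_pos,
            max_time, n_derived + n_ancestral);
  run_sim(S, n_ancestral);
  const int ntot = n_derived + n_ancestral;
  std::sort(S.muts.begin(), S.muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  const int ns = S.muts.size();
  NumericVector pos(ns);
  IntegerMatrix gt(ntot, ns);
  for (int j = 0; j < ns; ++j) {
    pos[j] = S.muts[j].pos;
    for (int i = 0; i < ntot; ++i) gt(i, j) = mhas(S.muts[j].m, i) ? 1 : 0;
  }
  return List::create(_["positions"] = pos, _["genotypes"] = gt);
}
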