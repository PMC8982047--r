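#include "demog.h"
#include <vector>
using namespace Rcpp;

// Forward-in-time simulation under the Poisson Random Field model.  Each
// generation g (with diploid size N_g given by sizes_fwd) receives
// Poisson(theta_g / 2) new mutations at copy number 1, where
// theta_g = theta_anc * N_g / n_anc.  Copy numbers evolve by Wright-Fisher
// binomial sampling around the selection-adjusted expected frequency.
// Returns the full per-generation copy-number histories of all mutations
// still segregating (0 < count < 2N) at the final generation.
// [[Rcpp::export]]
List cpp_simulate_prf(NumericVector sizes_fwd, double theta_anc, double n_anc,
                      double gamma, double h) {
  const int G = sizes_fwd.size();
  const double s = gamma / (2.0 * n_anc);  // homozygote coefficient 2s, with s = gamma/4N
  std::vector<std::vector<int> > hist;   // alive mutations only
  std::vector<int> origin;               // generation of origin (0-based)

  for (int g = 0; g < G; ++g) {
    // evolve existing mutations from generation g-1 into g
    if (g > 0) {
      const double twoN = 2.0 * sizes_fwd[g];
      const double twoNprev = 2.0 * sizes_fwd[g - 1];
      size_t i = 0;
      while (i < hist.size()) {
        int j = hist[i].back();
        double x = j / twoNprev;
        double xp = sel_freq(x, s, h);
        int jn = (int) R::rbinom(twoN, xp);
        if (jn <= 0 || jn >= (int) twoN) {
          // lost or fixed: drop (not segregating at the end)
          hist[i] = std::move(hist.back());
          origin[i] = origin.back();
          hist.pop_back();
          origin.pop_back();
        } else {
          hist[i].push_back(jn);
          ++i;
        }
      }
    }
    // inject new mutations at count 1
    double theta_g = theta_anc * sizes_fwd[g] / n_anc;
    int nnew = (int) R::rpois(theta_g / 2.0);
    for (int m = 0; m < nnew; ++m) {
      hist.push_back(std::vector<int>(1, 1));
      origin.push_back(g);
    }
  }

  const int nseg = hist.size();
  List counts(nseg);
  IntegerVector org(nseg);
  for (int i = 0; i < nseg; ++i) {
    counts[i] = IntegerVector(hist[i].begin(), hist[i].end());
    org[i] = origin[i] + 1;  // 1-based generation of origin
  }
  return List::create(_["counts"] = counts, _["origin_gen"] = org);
}

// Rejection sampling of allele-frequency trajectories conditioned on a
// present-day sample count within [lo, hi] out of S sampled chromosomes,
// under a constant population size N.  Exploits stationarity: mutations
// arise independently at rate theta/2 per generation, so every generation of
// an allele's segregating lifetime is an exchangeable candidate "present".
// All accepted candidates are returned (the pooled set is an unbiased draw
// from the stationary conditioned ensemble).
// [[Rcpp::export]]
List cpp_conditioned_constN(double N, double gamma, double h, int S,
                            int lo, int hi, int n_target, double max_alleles) {
  const double twoN = 2.0 * N;
  const double s = gamma / (2.0 * N);  // homozygote coefficient 2s, with s = gamma/4N
  std::vector<std::vector<int> > acc;
  std::vector<int> accK;
  double tried = 0.0;
  std::vector<int> traj;
  traj.reserve(4096);

  while ((int) acc.size() < n_target && tried < max_alleles) {
    tried += 1.0;
    traj.clear();
    int j = 1;
    traj.push_back(j);
    for (;;) {
      // candidate present at the current generation
      double x = j / twoN;
      int k = (int) R::rbinom((double) S, x);
      if (k >= lo && k <= hi) {
        acc.push_back(traj);
        accK.push_back(k);
        if ((int) acc.size() >= n_target) break;
      }
      double xp = sel_freq(x, s, h);
      int jn = (int) R::rbinom(twoN, xp);
      if (jn <= 0 || jn >= (int) twoN) break;  // absorbed next generation
      j = jn;
      traj.push_back(j);
    }
  }

  const int na = acc.size();
  List counts(na);
  IntegerVector kk(na);
  for (int i = 0; i < na; ++i) {
    counts[i] = IntegerVector(acc[i].begin(), acc[i].end());
    kk[i] = accK[i];
  }
  return List::create(_["counts"] = counts, _["k"] = kk,
                      _["alleles_tried"] = tried);
}

// Rejection sampling of conditioned trajectories under an arbitrary
// per-generation size vector (forward in time; the last entry is the
// present).  Mutations arise at a rate proportional to N_g, so the birth
// generation is drawn with probability proportional to sizes_fwd; the allele
// is then evolved to the present and retained iff a Binomial(S, x_present)
// sample count falls within [lo, hi].
// [[Rcpp::export]]
List cpp_conditioned_epochs(NumericVector sizes_fwd, double n_anc, double gamma,
                            double h, int S, int lo, int hi, int n_target,
                            double max_alleles) {
  const int G = sizes_fwd.size();
  const double s = gamma / (2.0 * n_anc);  // homozygote coefficient 2s, with s = gamma/4N
  std::vector<double> cum(G);
  double tot = 0.0;
  for (int g = 0; g < G; ++g) { tot += sizes_fwd[g]; cum[g] = tot; }

  std::vector<std::vector<int> > acc;
  std::vector<int> accK;
  double tried = 0.0;
  std::vector<int> traj;
  traj.reserve(4096);

  while ((int) acc.size() < n_target && tried < max_alleles) {
    tried += 1.0;
    double uu = R::unif_rand() * tot;
    int g0 = (int) (std::lower_bound(cum.begin(), cum.end(), uu) - cum.begin());
    if (g0 >= G) g0 = G - 1;
    traj.clear();
    int j = 1;
    traj.push_back(j);
    bool alive = true;
    for (int g = g0; g < G - 1; ++g) {
      double x = j / (2.0 * sizes_fwd[g]);
      double xp = sel_freq(x, s, h);
      double twoNn = 2.0 * sizes_fwd[g + 1];
      int jn = (int) R::rbinom(twoNn, xp);
      if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
      j = jn;
      traj.push_back(j);
    }
    if (!alive) continue;
    double xpres = j / (2.0 * sizes_fwd[G - 1]);
    int k = (int) R::rbinom((double) S, xpres);
    if (k >= lo && k <= hi) {
      acc.push_back(traj);
      accK.push_back(k);
    }
  }

  const int na = acc.size();
  List counts(na);
  IntegerVector kk(na);
  for (int i = 0; i < na; ++i) {
    counts[i] = IntegerVector(acc[i].begin(), acc[i].end());
    kk[i] = accK[i];
  }
  return List::create(_["counts"] = counts, _["k"] = kk,
                      _["alleles_tried"] = tried);
}

// Monte-Carlo counts for the Bayes'-rule link between the DFE of new
// mutations and the DFE of variants sampled at frequency f.  Each simulated
// mutation draws its scaled selection coefficient 4Ns from a gamma
// distribution over deleterious magnitudes (point4ns overrides with a point
// mass when not NA) and is classified by (a) its 4Ns bin and (b) whether a
// Binomial(S, x_present) sample count lands in [lo, hi] at the present.
// Ancient-epoch originations are handled by boundary stationarity: every
// segregating generation of an allele simulated under the ancient size is an
// exchangeable boundary state, each branched through the recent epochs to
// the present; one such trick-allele stands for `horizon_anc` naive
// originations, and recent-epoch originations are interleaved at rate
// N_g / N_anc per generation.  The horizon normalization cancels in the
// Bayes'-rule reconstruction, and all probabilities derive from the same
// counts so the reconstruction identity is exact on them.
// [[Rcpp::export]]
List cpp_freq_conditionals(double N_anc, NumericVector recent_sizes,
                           double horizon_anc, double h, int S, int lo,
                           int hi, double shape, double scale,
                           double point4ns, NumericVector bin_lower,
                           double n_alleles) {
  const double twoNa = 2.0 * N_anc;
  const int T = recent_sizes.size();
  const int B = bin_lower.size();
  double w_recent = 0.0;
  for (int g = 0; g < T; ++g) w_recent += recent_sizes[g] / N_anc;

  NumericVector n_total(B), n_at_f(B);
  double sum_g_at_f = 0.0, n_acc = 0.0;
  double owe_recent = 0.0;

  for (double m = 0.0; m < n_alleles; m += 1.0) {
    // recent-epoch originations owed for this ancient trick-allele
    owe_recent += w_recent;
    while (owe_recent >= 1.0) {
      owe_recent -= 1.0;
      double g4 = ISNA(point4ns) ? R::rgamma(shape, scale) : point4ns;
      int b = B - 1;
      for (int i = 0; i < B - 1; ++i)
        if (g4 < bin_lower[i + 1]) { b = i; break; }
      n_total[b] += 1.0;
      double s = -g4 / (2.0 * N_anc);
      double uu = R::unif_rand() * w_recent;
      int g0 = 0;
      double accw = 0.0;
      for (int g = 0; g < T; ++g) {
        accw += recent_sizes[g] / N_anc;
        if (uu < accw) { g0 = g; break; }
      }
      int j = 1;
      bool alive = true;
      for (int g = g0; g < T - 1; ++g) {
        double x = j / (2.0 * recent_sizes[g]);
        double twoNn = 2.0 * recent_sizes[g + 1];
        int jn = (int) R::rbinom(twoNn, sel_freq(x, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        j = jn;
      }
      if (!alive) continue;
      int k = (int) R::rbinom((double) S, j / (2.0 * recent_sizes[T - 1]));
      if (k >= lo && k <= hi) {
        n_at_f[b] += 1.0;
        sum_g_at_f += g4;
        n_acc += 1.0;
      }
    }
    // ancient trick-allele: one per `horizon_anc` naive originations
    double g4 = ISNA(point4ns) ? R::rgamma(shape, scale) : point4ns;
    int b = B - 1;
    for (int i = 0; i < B - 1; ++i)
      if (g4 < bin_lower[i + 1]) { b = i; break; }
    n_total[b] += horizon_anc;
    double s = -g4 / (2.0 * N_anc);
    int j = 1;
    for (;;) {
      // branch a copy through the recent epochs (or test directly at T = 0)
      int jc = j;
      bool alive = true;
      double xprev = jc / twoNa;
      for (int g = 0; g < T; ++g) {
        double twoNn = 2.0 * recent_sizes[g];
        int jn = (int) R::rbinom(twoNn, sel_freq(xprev, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        jc = jn;
        xprev = jc / twoNn;
      }
      if (alive) {
        int k = (int) R::rbinom((double) S, xprev);
        if (k >= lo && k <= hi) {
          n_at_f[b] += 1.0;
          sum_g_at_f += g4;
          n_acc += 1.0;
        }
      }
      double x = j / twoNa;
      int jn = (int) R::rbinom(twoNa, sel_freq(x, s, h));
      if (jn <= 0 || jn >= (int) twoNa) break;
      j = jn;
    }
  }

  return List::create(_["n_total"] = n_total, _["n_at_f"] = n_at_f,
                      _["n_mut"] = (double) sum(n_total),
                      _["sum_4ns_at_f"] = sum_g_at_f);
}

// Conditioned trajectories under a multi-epoch model via boundary
// stationarity.  The open-ended most ancient epoch is at mutation-selection
// balance at its boundary with the recent epochs, so every generation of an
// allele's segregating lifetime under the ancient size is an exchangeable
// draw of a boundary state; each candidate state is evolved through the
// per-generation recent sizes to the present and retained iff a
// Binomial(S, x_present) sample count lands in [lo, hi].  Originations
// inside the recent epochs are interleaved at their correct relative rate
// (proportional to N_g per generation).
// [[Rcpp::export]]
List cpp_conditioned_boundary(double N_anc, NumericVector recent_sizes,
                              double gamma, double h, int S, int lo, int hi,
                              int n_target, double max_alleles) {
  const double twoNa = 2.0 * N_anc;
  const double s = gamma / (2.0 * N_anc);  // homozygote 2s, s = gamma/4N
  const int T = recent_sizes.size();
  double w_recent = 0.0;  // recent originations per ancient trick-allele
  for (int g = 0; g < T; ++g) w_recent += recent_sizes[g] / N_anc;

  std::vector<std::vector<int> > acc;
  std::vector<int> accK;
  double tried = 0.0, owe_recent = 0.0;
  std::vector<int> traj, cand;
  traj.reserve(4096);

  while ((int) acc.size() < n_target && tried < max_alleles) {
    tried += 1.0;
    // recent-epoch originations owed for this ancient allele
    owe_recent += w_recent;
    while (owe_recent >= 1.0 && (int) acc.size() < n_target) {
      owe_recent -= 1.0;
      // birth generation within the recent epochs, proportional to N_g
      double uu = R::unif_rand() * w_recent;
      int g0 = 0;
      double accw = 0.0;
      for (int g = 0; g < T; ++g) {
        accw += recent_sizes[g] / N_anc;
        if (uu < accw) { g0 = g; break; }
      }
      cand.assign(1, 1);
      int j = 1;
      bool alive = true;
      for (int g = g0; g < T - 1; ++g) {
        double x = j / (2.0 * recent_sizes[g]);
        double twoNn = 2.0 * recent_sizes[g + 1];
        int jn = (int) R::rbinom(twoNn, sel_freq(x, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        j = jn;
        cand.push_back(j);
      }
      if (!alive) continue;
      int k = (int) R::rbinom((double) S, j / (2.0 * recent_sizes[T - 1]));
      if (k >= lo && k <= hi) { acc.push_back(cand); accK.push_back(k); }
    }
    // ancient trick-allele: every segregating generation is a boundary state
    traj.clear();
    int j = 1;
    traj.push_back(j);
    for (;;) {
      // branch a copy through the recent epochs
      int jc = j;
      bool alive = true;
      cand = traj;
      double xprev = jc / twoNa;
      for (int g = 0; g < T; ++g) {
        double twoNn = 2.0 * recent_sizes[g];
        int jn = (int) R::rbinom(twoNn, sel_freq(xprev, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        jc = jn;
        cand.push_back(jc);
        xprev = jc / twoNn;
      }
      if (alive) {
        int k = (int) R::rbinom((double) S, xprev);
        if (k >= lo && k <= hi) {
          acc.push_back(cand);
          accK.push_back(k);
          if ((int) acc.size() >= n_target) break;
        }
      }
      // advance the ancient-epoch allele itself
      double x = j / twoNa;
      int jn = (int) R::rbinom(twoNa, sel_freq(x, s, h));
      if (jn <= 0 || jn >= (int) twoNa) break;
      j = jn;
      traj.push_back(j);
    }
  }

  const int na = acc.size();
  List counts(na);
  IntegerVector kk(na);
  for (int i = 0; i < na; ++i) {
    counts[i] = IntegerVector(acc[i].begin(), acc[i].end());
    kk[i] = accK[i];
  }
  return List::create(_["counts"] = counts, _["k"] = kk,
                      _["alleles_tried"] = tried);
}

// Joint sampling of (4Ns, trajectory) pairs for variants found at the
// target sample frequency when new mutations draw their deleterious 4Ns
// magnitude from a gamma DFE.  Identical to cpp_conditioned_boundary except
// that every simulated origination draws its own selection coefficient, so
// pooled accepted candidates are draws from the joint conditioned ensemble
// (the DFEf filtering arises naturally from differential acceptance).
// [[Rcpp::export]]
List cpp_conditioned_dfe(double N_anc, NumericVector recent_sizes,
                         double shape, double scale, double h, int S,
                         int lo, int hi, int n_target, double max_alleles) {
  const double twoNa = 2.0 * N_anc;
  const int T = recent_sizes.size();
  double w_recent = 0.0;
  for (int g = 0; g < T; ++g) w_recent += recent_sizes[g] / N_anc;

  std::vector<std::vector<int> > acc;
  std::vector<int> accK;
  std::vector<double> accG;
  double tried = 0.0, owe_recent = 0.0;
  std::vector<int> traj, cand;
  traj.reserve(4096);

  while ((int) acc.size() < n_target && tried < max_alleles) {
    tried += 1.0;
    owe_recent += w_recent;
    while (owe_recent >= 1.0 && (int) acc.size() < n_target) {
      owe_recent -= 1.0;
      double g4 = -R::rgamma(shape, scale);
      double s = g4 / (2.0 * N_anc);
      double uu = R::unif_rand() * w_recent;
      int g0 = 0;
      double accw = 0.0;
      for (int g = 0; g < T; ++g) {
        accw += recent_sizes[g] / N_anc;
        if (uu < accw) { g0 = g; break; }
      }
      cand.assign(1, 1);
      int j = 1;
      bool alive = true;
      for (int g = g0; g < T - 1; ++g) {
        double x = j / (2.0 * recent_sizes[g]);
        double twoNn = 2.0 * recent_sizes[g + 1];
        int jn = (int) R::rbinom(twoNn, sel_freq(x, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        j = jn;
        cand.push_back(j);
      }
      if (!alive) continue;
      int k = (int) R::rbinom((double) S, j / (2.0 * recent_sizes[T - 1]));
      if (k >= lo && k <= hi) {
        acc.push_back(cand); accK.push_back(k); accG.push_back(g4);
      }
    }
    double g4 = -R::rgamma(shape, scale);
    double s = g4 / (2.0 * N_anc);
    traj.clear();
    int j = 1;
    traj.push_back(j);
    for (;;) {
      int jc = j;
      bool alive = true;
      cand = traj;
      double xprev = jc / twoNa;
      for (int g = 0; g < T; ++g) {
        double twoNn = 2.0 * recent_sizes[g];
        int jn = (int) R::rbinom(twoNn, sel_freq(xprev, s, h));
        if (jn <= 0 || jn >= (int) twoNn) { alive = false; break; }
        jc = jn;
        cand.push_back(jc);
        xprev = jc / twoNn;
      }
      if (alive) {
        int k = (int) R::rbinom((double) S, xprev);
        if (k >= lo && k <= hi) {
          acc.push_back(cand); accK.push_back(k); accG.push_back(g4);
          if ((int) acc.size() >= n_target) break;
        }
      }
      double x = j / twoNa;
      int jn = (int) R::rbinom(twoNa, sel_freq(x, s, h));
      if (jn <= 0 || jn >= (int) twoNa) break;
      j = jn;
      traj.push_back(j);
    }
  }

  const int na = acc.size();
  List counts(na);
  IntegerVector kk(na);
  NumericVector gg(na);
  for (int i = 0; i < na; ++i) {
    counts[i] = IntegerVector(acc[i].begin(), acc[i].end());
    kk[i] = accK[i];
    gg[i] = accG[i];
  }
  return List::create(_["counts"] = counts, _["k"] = kk, _["gamma"] = gg,
                      _["alleles_tried"] = tried);
}
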