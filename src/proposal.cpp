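#include "demog.h"
#include <vector>
using namespace Rcpp;

// log Beta-Binomial(m | size, a, b) pmf
static inline double lbetabinom(double m, double size, double a, double b) {
  return R::lchoose(size, m) + R::lbeta(m + a, size - m + b) - R::lbeta(a, b);
}

// Backward-in-time proposal for allele-frequency trajectories ending at a
// present-day sample count within [lo, hi] of S chromosomes.  The present
// sample count is uniform on the band; the present population count is
// beta-binomial (the posterior of the population frequency given the sample
// count under a uniform prior).  Earlier counts follow a defensive
// two-component mixture of time-reversed Wright-Fisher kernels.  The main
// component decays toward the origin at the strength |gamma_prop|,
// mirroring the younger ages of selected alleles conditioned on a low
// present-day frequency.  The second component covers older histories:
// within the recent epochs (t < t_anc) it reverses the true selective drift
// (capped, so strong post-expansion selection cannot explode backward) --
// a deleterious allele declining forward rises going backward -- and in the
// open-ended ancient epoch it decays at a quarter strength.  The mixture
// density of each realized path is accumulated under both kernels.
// Trajectories absorbed at fixation, or at zero while above count 1, are
// rejected and regenerated; the rejection constant is shared by all draws
// of one proposal and cancels in the self-normalized estimator.
// [[Rcpp::export]]
List cpp_propose_trajectories(NumericVector sizes_bp, NumericVector ends_bp,
                              double n_anc, double gamma_prop, double h, int S,
                              int lo, int hi, int K, double max_age,
                              double max_tries, double t_anc) {
  const double shom = gamma_prop / (2.0 * n_anc);  // homozygote 2s
  const double sdecay = -std::fabs(shom);
  const double scap = 50.0 / (2.0 * n_anc);
  const double srev = (shom >= 0) ? -std::min(shom, scap)
                                  : std::min(-shom, scap);
  const double w1 = 0.75;  // mixture weight of the decay component
  List counts(K);
  IntegerVector kk(K);
  NumericVector logq(K);
  double tries = 0.0;
  int got = 0;
  std::vector<int> rev;
  rev.reserve(4096);

  while (got < K) {
    if (++tries > max_tries)
      stop("backward proposal failed: retry budget exhausted (%.0f attempts for %d trajectories)",
           tries, K);
    // present-day sample count, uniform over the accepted band
    int k = lo + (int) std::floor(R::unif_rand() * (hi - lo + 1));
    if (k > hi) k = hi;
    double lq = -std::log((double) (hi - lo + 1));
    double twoN0 = 2.0 * size_bp(0.0, sizes_bp, ends_bp);
    // present-day population count: beta-binomial, truncated to (0, 2N)
    double p = R::rbeta(k + 1.0, S - k + 1.0);
    int j0 = (int) R::rbinom(twoN0, p);
    if (j0 <= 0 || j0 >= (int) twoN0) continue;
    double l0 = lbetabinom(0.0, twoN0, k + 1.0, S - k + 1.0);
    double lfull = lbetabinom(twoN0, twoN0, k + 1.0, S - k + 1.0);
    lq += lbetabinom((double) j0, twoN0, k + 1.0, S - k + 1.0)
        - std::log1p(-(std::exp(l0) + std::exp(lfull)));

    rev.clear();
    rev.push_back(j0);
    int j = j0;
    double t = 0.0;
    bool ok = true;
    bool use1 = (R::unif_rand() < w1);
    double lq1 = 0.0, lq2 = 0.0;
    for (;;) {
      double twoNt = 2.0 * size_bp(t, sizes_bp, ends_bp);
      double twoNp = 2.0 * size_bp(t + 1.0, sizes_bp, ends_bp);
      double x = j / twoNt;
      bool recent = (t + 1.0 <= t_anc);
      double xq1 = sel_freq(x, sdecay, h);
      double xq2 = sel_freq(x, recent ? srev : 0.25 * sdecay, h);
      int jn = (int) R::rbinom(twoNp, use1 ? xq1 : xq2);
      lq1 += R::dbinom(jn, twoNp, xq1, 1);
      lq2 += R::dbinom(jn, twoNp, xq2, 1);
      if (jn == 0) {
        if (j == 1) break;          // origin reached at count 1
        ok = false; break;          // impossible origination
      }
      if (jn >= (int) twoNp) { ok = false; break; }  // fixation backward
      rev.push_back(jn);
      j = jn;
      t += 1.0;
      if (t > max_age) { ok = false; break; }
    }
    if (!ok) continue;
    // path density under the mixture of the two kernels
    double lmax = std::max(lq1 + std::log(w1), lq2 + std::log(1.0 - w1));
    lq += lmax + std::log(std::exp(lq1 + std::log(w1) - lmax) +
                          std::exp(lq2 + std::log(1.0 - w1) - lmax));

    IntegerVector cc(rev.size());
    for (int i = 0; i < (int) rev.size(); ++i)
      cc[i] = rev[rev.size() - 1 - i];  // origin -> present
    counts[got] = cc;
    kk[got] = k;
    logq[got] = lq;
    ++got;
  }
  return List::create(_["counts"] = counts, _["k"] = kk, _["logq"] = logq,
                      _["tries"] = tries);
}

// Log target density of a trajectory under the Poisson Random Field /
// Wright-Fisher model with selection, up to 4Ns-independent constants:
// origination mass proportional to the population size at the origin, the
// product of per-generation binomial transition probabilities, and the
// binomial probability of the observed present-day sample count.
// [[Rcpp::export]]
NumericVector cpp_log_target(List counts_list, IntegerVector kvec,
                             NumericVector sizes_bp, NumericVector ends_bp,
                             double n_anc, double gamma, double h, int S) {
  const int K = counts_list.size();
  const double s = gamma / (2.0 * n_anc);  // homozygote coefficient 2s, with s = gamma/4N
  NumericVector out(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector cc = counts_list[i];
    const int A = cc.size();
    double lt = std::log(size_bp(A - 1.0, sizes_bp, ends_bp) / n_anc);
    bool ok = true;
    for (int g = 0; g < A - 1 && ok; ++g) {
      double tg = A - 1.0 - g;             // gens before present of cc[g]
      double twoN = 2.0 * size_bp(tg, sizes_bp, ends_bp);
      double twoNn = 2.0 * size_bp(tg - 1.0, sizes_bp, ends_bp);
      if (cc[g] <= 0 || cc[g] >= (int) twoN) { ok = false; break; }
      double x = cc[g] / twoN;
      double xp = sel_freq(x, s, h);
      lt += R::dbinom((double) cc[g + 1], twoNn, xp, 1);
    }
    if (ok) {
      double twoN0 = 2.0 * size_bp(0.0, sizes_bp, ends_bp);
      if (cc[A - 1] <= 0 || cc[A - 1] >= (int) twoN0) ok = false;
      else lt += R::dbinom((double) kvec[i], (double) S, cc[A - 1] / twoN0, 1);
    }
    out[i] = ok ? lt : R_NegInf;
  }
  return out;
}
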