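#ifndef HAPLODFE_DEMOG_H
#define HAPLODFE_DEMOG_H

#include <Rcpp.h>

// Diploid population size at t generations before the present, from
// recent-first epoch sizes and cumulative epoch end times (ends[i] =
// generations before present at which epoch i ends).  Times at or beyond the
// last recorded end fall into the open-ended most ancient epoch.
static inline double size_bp(double t, const Rcpp::NumericVector& sizes,
                             const Rcpp::NumericVector& ends) {
  const int k = sizes.size();
  for (int i = 0; i < k - 1; ++i)
    if (t < ends[i]) return sizes[i];
  return sizes[k - 1];
}

// Expected derived-allele frequency after one generation of viability
// selection with coefficient s and dominance h (fitnesses 1 : 1+sh : 1+s).
static inline double sel_freq(double x, double s, double h) {
  if (s == 0.0 || x <= 0.0 || x >= 1.0) return x;
  double num = x * (1.0 + s * h + s * (1.0 - h) * x);
  double den = 1.0 + 2.0 * s * h * x * (1.0 - x) + s * x * x;
  double xp = num / den;
  if (xp < 0.0) xp = 0.0;
  if (xp > 1.0) xp = 1.0;
  return xp;
}

#endif
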