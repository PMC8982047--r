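---
title: "Inferring selection and the DFE from pairwise IBS haplotype lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection and the DFE from pairwise IBS haplotype lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

Low-frequency variants carry a haplotypic signature of the selection acting
on them.  An allele observed today at, say, 1% sample frequency is young if
it is strongly selected (in either direction, under a constant population
size) and old if it is neutral; younger alleles sit on longer shared
haplotypes because fewer mutations have had time to accumulate between the
chromosomes that carry them.  `haplodfe` turns that signature into
likelihood-based estimates of

* a point population-scaled selection coefficient `4Ns` shared by a set of
  focal variants at one sample frequency `f`,
* the distribution of fitness effects of the variants segregating at `f`
  (the "DFEf"), parameterized as a discretized gamma over `|4Ns|`, and
* the distribution of fitness effects of new mutations (the DFE), obtained
  from the DFEf by Bayes' rule,

with a rejection-ABC step to estimate a piecewise-constant demography from
putatively neutral variants first.

The data statistic is the pairwise identity-by-state (IBS) length `L`: the
distance in bp from the focal derived allele to the first site at which a
pair of derived-carrying haplotypes differs, measured upstream and
downstream.  Lengths are binned into `M` half-open windows (default
`(0, 50kb], ..., (200kb, 250kb], (250kb, Inf)`); with `A` loci and `n`
carriers per locus the data are `2 A choose(n, 2)` binned records.

## Model and likelihood

The likelihood of `4Ns` for a record in window `w_j` integrates over the
allele-frequency trajectory `H` of the focal allele:

    L(4Ns, f, D | L in w_j) = Int P(L in w_j | D, H) P(H | 4Ns, f, D) dH

where `D` is the demography.  `P(H | 4Ns, f, D)` is the Wright-Fisher /
Poisson Random Field law of the trajectory of a derived allele conditioned
on its present-day sample frequency; `P(L in w_j | D, H)` is estimated by
simulating haplotypes under a structured coalescent conditional on `H`.
The composite likelihood of the data multiplies record likelihoods as if
independent; the point estimate is a grid search over `4Ns` in `[-200,
200]`, and uncertainty comes from a locus-level bootstrap (records within a
locus share a trajectory and are strongly correlated, so no analytic
standard errors are reported).

The DFEf extends the same machinery: the per-record likelihood becomes a
mixture over integer `|4Ns|` in `[0, tau]` weighted by a discretized gamma
with shape `alpha` and scale `beta`, whose upper tail is collapsed onto
`tau`.  The fit is a grid search over `(alpha, beta)`; as in the original
formulation the two parameters trade off strongly along `alpha * beta =
const`, and it is the implied mean of the DFEf that is stably estimated.

The DFE of new mutations follows from the DFEf by Bayes' rule per
selection bin `s_j`:

    P(s_j) = P(s_j | f, D) * P(f | D) / P(f | s_j, D)

with the two frequency conditionals estimated by forward simulation under
the candidate DFE.  All three quantities are computed from the same
simulation counts, which makes the reconstruction an exact algebraic
identity on those counts and lets the (arbitrary) origination horizon
cancel.

## Selection convention

Genotype fitnesses are `1 : 1 + s : 1 + 2s` (codominant by default; the
dominance parameter generalizes to `1 : 1 + 2hs : 1 + 2s`), with
`s = gamma / 4N` defined by the most ancient epoch's diploid size `N`.
This is the standard population-genetic convention: it reproduces Kimura's
fixation probability `u = (1 - exp(-gamma/2N)) / (1 - exp(-gamma))`, which
we use as a calibration check in development.  `s` is constant per
generation across epochs, so after a 10-fold expansion the effective scaled
coefficient is `10 gamma` — the source of the sign information that a
constant-size history lacks.

A caution on the literature figure of an "approximately 8-fold" age
difference between neutral and `|4Ns| = 100` variants at 1% frequency: the
exact Wright-Fisher value of that ratio is close to 4.  We computed it
three independent ways — an exact transition-matrix calculation, forward
simulation with a final-generation snapshot, and the package's conditioned
sampler — and all agree.  The 8-fold figure coincides with a
strong-selection asymptotic formula for the mean age, `(1/s)(log(gamma x) +
0.577)`, evaluated at `gamma x = 1` where it is far outside its domain of
validity.  The package reports what the model actually implies.

## Simulators

**Forward PRF.** `simulate_prf()` injects `Poisson(theta/2)` new mutations
per generation (scaled by the current population size) and evolves copy
numbers by binomial sampling around the selection-adjusted expected
frequency; `condition_on_frequency()` retains trajectories whose binomial
present-day sample count lands in the accepted band.

**Conditioned rejection sampling.** Drawing many trajectories conditioned
at `f` through a literal forward run is wasteful, so
`sample_trajectories_at_frequency()` uses two exact reformulations.  Under
a constant size, the mutation influx is stationary, so every segregating
generation of an independently simulated allele is an exchangeable
candidate "present"; pooled accepted candidates are an unbiased draw from
the conditioned ensemble (candidates from one allele share history, which
leaves means unbiased and slightly inflates Monte-Carlo error; we verified
the sampler against an exact transition-matrix oracle).  Under multi-epoch
models, the open-ended ancient epoch is at mutation-selection balance at
its boundary with the recent epochs, so the same trick yields boundary
states that are then evolved through the recent epochs; originations inside
the recent epochs are interleaved at their correct relative rate.

**Importance sampling.** Likelihood tables need trajectories for every grid
`4Ns`, including values where rejection sampling is hopeless.
`propose_trajectories()` generates trajectories backward from the present:
the sample count uniform on the band, the population count from its
beta-binomial posterior, and earlier counts from a defensive mixture of two
time-reversed Wright-Fisher kernels — a decay kernel of strength
`|4Ns|/4N` (conditioned alleles are young) and a milder component that
covers older histories (capped drift reversal inside recent epochs, where a
declining deleterious allele rises backward in time).  Weights against the
target density `P(H | 4Ns, f, D)` are self-normalized, and every table
entry carries its effective sample size `ESS = (sum w)^2 / sum w^2`.  Grid
points with `ESS < 100` are masked, never silently reported — mirroring the
original method's treatment of strongly deleterious values under
expansion-like histories, where backward proposals overlap the target
poorly.  The ESS at a fixed `K` is itself stochastic; harness code rebuilds
low-ESS grid points with fresh Monte Carlo rather than lowering the gate.

**Conditional coalescent.** `simulate_haplotypes()` runs a discrete
two-class structured coalescent backward along the trajectory: lineages
pick parents within their allelic class (derived class size = trajectory
count, handling simultaneous multiple mergers exactly when class sizes are
small), recombination splits ancestral material at rate `r` per bp per
generation with the non-focal piece rejoining the derived class with
probability equal to the current derived frequency, and the last derived
lineage transfers to the ancestral class at the origin.  Mutations drop on
branches at `u` per bp per generation under infinite sites.  Generations
with slowly varying rates are traversed by hazard accumulation (one
exponential draw per event), and sample-descent masks prune material that
has found its MRCA.

**Sampling convention.** Sampled chromosomes pick present-day population
copies with replacement — the binomial-sampling view of a cohort, which at
rescaled population sizes (tens of derived copies) matters: two sampled
carriers can be copies of the same chromosome.  The convention is applied
identically when building tables and when generating data, and it makes the
marginal distribution of a pair's IBS window independent of how many
haplotypes are simulated jointly.  Tables therefore simulate independent
pairs (`n_sim = 2`), which permits an aggressive pruning: once the pair
differs at distance `d`, material beyond `d` is discarded.  This is
20-50x faster than simulating full haplotype sets with no change in the
estimated probabilities (checked against pooled `n = 20` simulations).

## Study conditions and reduced-scale defaults

The package's reference conditions mirror the original study's, rescaled
for desk-scale computation by dividing population sizes by 10 and
multiplying `u`, `r` and `s` by 10, which preserves `4Ns`, `theta = 4Nul`
and `rho = 4Nrl` (epoch durations are kept, following the printed
description of the rescaling):

* constant size: `N = 1,000` (from 10,000), `u = 1.2e-7`, `r = 1e-7`,
  `l = 500 kb`, so `theta = 240`, `rho = 200`; sample `S = 4,000`
  chromosomes at `f = 1%` (40 carriers), `n = 20` used for IBS;
* expansion: `500 -> 5,000` at 100 generations before present (from
  `5,000 -> 50,000`), same locus rates scaled from `u = 1.2e-8`,
  `r = 1e-8`;
* burn-in `10 N` generations for forward simulation, per the
  mutation-selection-balance requirement;
* window scheme: five 50-kb windows plus the open-ended sixth;
* grids: step 10 (constant) / 25 (expansion) over `[-200, 200]` for point
  estimates, step 1 over `[0, tau]` for the DFEf; `K = 2,000` trajectories
  per grid point; 250 pairs (tables for point estimates) or 100 pairs
  (DFEf tables) per trajectory; `tau` follows the contiguous `ESS >= 100`
  coverage of the table, the same rule the original analysis applied when
  deeply deleterious values lacked resolution;
* recovery harnesses: `A = 50` loci and 40 replicates per true `4Ns`
  (constant and expansion), `A = 150` loci for DFEf runs with a Boyko-type
  human DFE (gamma over `|4Ns|` with shape 0.184, scale 1599.313 on the
  expansion model's scale); ABC at 500 prior draws, acceptance quantile
  0.05, `A = 50` loci and 40 summary pairs per locus, log-uniform size
  prior on `[250, 4000]`.
* likelihood tables are smoothed across the 4Ns grid (ESS-weighted local
  regression per window, rows renormalized) after any low-ESS points are
  rebuilt with fresh Monte Carlo.  The underlying window probabilities are
  smooth in `4Ns` while raw grid points carry independent Monte-Carlo
  noise whose scale at `K = 2,000` trajectories is comparable to the
  between-point signal; smoothing removes most of it without touching the
  sampling budgets.

These sizes were chosen once, to keep the full validation suite within a
desktop budget while leaving each check enough resolution to fail
informatively; they are stated here as the package's own study conditions.

What the synthetic generator does *not* emulate: linked selection between
neighboring focal loci, gene conversion, phasing or genotyping error,
ancestral-state misidentification, and variable mutation rates along the
region.  Passing recovery tests on this generator therefore demonstrates
internal consistency of the method under its own model, not robustness to
those real-data complications (the original study examined them
separately).

## Numerical choices and degenerate inputs

* Log-space weights normalized by their maximum; impossible transitions
  give zero weight rather than errors.
* Windows with zero estimated probability are floored at
  `1 / (10 K reps choose(n,2))` before taking logs, with a warning; the
  argmax is insensitive to the floor whenever no observed window sits below
  it (asserted in the tests by recomputation at `eps / 10`).
* Flat likelihood surfaces tie-break toward neutrality (smallest `|4Ns|`,
  then negative before positive).
* Trajectories proposed backward that hit fixation, or reach zero from a
  count above one, are rejected and regenerated; the shared rejection
  constant cancels in the self-normalized estimator.
* `pairwise_ibs_length()` treats sites with missing genotypes in either
  haplotype as non-informative; a length exactly at a window boundary
  belongs to the lower window; the no-difference sentinel falls in the
  final window.
* The ABC observed summary is computed by the same pooled-pair summary
  path as the simulated summaries, the usual requirement that data and
  simulations pass through one summary definition.
* Bootstrap resampling is by whole locus; replicates that fail are dropped
  and counted, and the run errors if more than 10% drop.

## Known limitations

* The sign of `4Ns` is unidentifiable under a constant-size history; the
  method reports magnitudes faithfully and the sign only where the
  demography provides it (e.g. recent expansions).
* At the reduced scale (`A = 50` loci), single-replicate point estimates of
  `4Ns` are noisy (quartiles spanning tens of units); medians over
  replicates are the meaningful summary, as in the original evaluation.
* ESS of the backward proposal degrades for strongly deleterious values
  under expansion histories; affected grid points are masked and `tau` is
  limited accordingly.  Better proposals (e.g. Wright-Fisher bridges) are
  the natural extension.
* The DFEf assumes neutral-or-deleterious variants only; a mixed DFE with
  advantageous mass is out of scope.
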