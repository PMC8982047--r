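#' Backward-in-time trajectory proposals at a target sample frequency
#'
#' Samples `K` allele-frequency trajectories that all end within the accepted
#' present-day sample-frequency band, by generating the copy number backward
#' in time from the present until loss (count 1 at the origin).  The present
#' sample count is uniform on the accepted band, the present population
#' count is drawn from its beta-binomial posterior given the sample count,
#' and earlier counts follow a time-reversed Wright-Fisher kernel in which
#' the magnitude of `proposal_selection` acts as a decay toward the origin
#' (selected alleles conditioned on a low present-day frequency are younger
#' than neutral ones, symmetrically in the sign of 4Ns under a constant
#' size).  Each trajectory carries the log-density of its own generation
#' under the proposal.
#'
#' Proposals absorbed at fixation going backward, or reaching count 0 from a
#' count above 1, are rejected and regenerated; the shared rejection
#' constant cancels in the self-normalized importance-sampling estimator.
#'
#' @param sample a [sample_config()].
#' @param demography a [demographic_model()].
#' @param proposal_selection a [selection_params()] or 4Ns value used to
#'   shape the proposal (usually the grid point being evaluated).
#' @param K number of trajectories.
#' @param seed integer seed or `NULL`.
#' @param max_age cap on proposed trajectory ages, generations.
#' @param max_tries total retry budget (default `100 * K`).
#' @return a `proposal_set`: counts, final sample counts `k`, proposal
#'   log-densities `logq`.
#' @export
propose_trajectories <- function(sample, demography, proposal_selection, K,
                                 seed = NULL,
                                 max_age = 50 * ancient_size(demography),
                                 max_tries = 100 * K) {
  stopifnot(inherits(sample, "sample_config"), K >= 1)
  proposal_selection <- .as_selection(proposal_selection)
  .hd_set_seed(seed)
  band <- .band_counts(sample$S, sample$f, sample$tolerance)
  bp <- .demog_bp(demography)
  t_anc <- if (length(demography$sizes) > 1) sum(demography$durations[-1]) else 0
  res <- cpp_propose_trajectories(bp$sizes, pmin(bp$ends, .Machine$double.xmax),
                                  ancient_size(demography),
                                  proposal_selection$gamma,
                                  proposal_selection$dominance,
                                  sample$S, band[1], band[2], as.integer(K),
                                  max_age, max_tries, t_anc)
  structure(list(counts = res$counts, final_sample_count = res$k,
                 logq = res$logq, demography = demography, sample = sample,
                 proposal_selection = proposal_selection,
                 tries = res$tries),
            class = c("proposal_set", "trajectory_set"))
}

#' Log target density of a conditioned trajectory
#'
#' Log of the origination probability (proportional to the population size
#' at the origin generation), times the product of per-generation
#' Wright-Fisher binomial transition probabilities, times the binomial
#' probability of the observed present-day sample count, up to
#' 4Ns-independent constants (which cancel in the self-normalized
#' importance-sampling estimator).  Impossible transitions give `-Inf`.
#'
#' @param trajectories a `trajectory_set`/`proposal_set` with
#'   `final_sample_count`, or a list of counts vectors.
#' @param selection a [selection_params()] or 4Ns value.
#' @param demography a [demographic_model()].
#' @param sample a [sample_config()].
#' @param final_sample_count needed when `trajectories` is a bare list.
#' @return numeric vector of log-densities.
#' @export
log_target_density <- function(trajectories, selection, demography, sample,
                               final_sample_count = NULL) {
  selection <- .as_selection(selection)
  if (inherits(trajectories, "trajectory_set")) {
    counts <- trajectories$counts
    if (is.null(final_sample_count))
      final_sample_count <- trajectories$final_sample_count
  } else counts <- trajectories
  if (is.null(final_sample_count))
    stop("final_sample_count is required to evaluate the target density")
  bp <- .demog_bp(demography)
  cpp_log_target(counts, as.integer(final_sample_count), bp$sizes,
                 pmin(bp$ends, .Machine$double.xmax),
                 ancient_size(demography), selection$gamma,
                 selection$dominance, sample$S)
}

#' Effective sample size of importance weights
#'
#' `ESS = (sum w)^2 / sum w^2`, computed on normalized weights; lies in
#' `[1, K]` for `K` weights.
#'
#' @param weights nonnegative weights (or log-weights with `log = TRUE`).
#' @param log interpret `weights` as log-weights.
#' @export
ess <- function(weights, log = FALSE) {
  if (log) {
    weights <- weights[is.finite(weights) | weights == -Inf]
    m <- max(weights)
    if (!is.finite(m)) stop("all weights are zero")
    weights <- exp(weights - m)
  }
  if (length(weights) == 0 || !any(weights > 0) || any(weights < 0) ||
      any(!is.finite(weights)))
    stop("weights must be nonnegative, finite and not all zero")
  sum(weights)^2 / sum(weights^2)
}

#' Self-normalized importance weights for a proposal set
#'
#' @param proposal a `proposal_set` from [propose_trajectories()].
#' @param selection target [selection_params()] or 4Ns value.
#' @return list with normalized weights `w` (summing to 1), `log_w`
#'   (unnormalized, max subtracted), and `ess`.
#' @export
importance_weights <- function(proposal, selection) {
  stopifnot(inherits(proposal, "proposal_set"))
  lt <- log_target_density(proposal, selection, proposal$demography,
                           proposal$sample)
  lw <- lt - proposal$logq
  if (all(lw == -Inf)) stop("all importance weights are zero")
  m <- max(lw[is.finite(lw)])
  w <- exp(lw - m)
  w[!is.finite(w)] <- 0
  list(w = w / sum(w), log_w = lw - m, ess = ess(w))
}
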