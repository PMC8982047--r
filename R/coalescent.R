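# generous backward-time cap for the conditional coalescent: deep enough for
# the grand MRCA under the largest epoch with slack
.coal_time_cap <- function(demography) {
  500 * max(demography$sizes) + 1e5
}

#' Simulate haplotypes conditional on an allele-frequency trajectory
#'
#' Backward-in-time two-class structured coalescent with recombination and
#' infinite-sites mutation: `n` sampled lineages start in the derived class
#' (all carrying the focal allele), coalesce within allelic classes whose
#' sizes follow the trajectory (derived: copy count; ancestral: `2N - count`),
#' recombine at rate `r` per bp of ancestral-material span per generation
#' (the piece without the focal site rejoins the derived class with
#' probability equal to the current derived frequency), transfer to the
#' ancestral class at the origin generation, and continue as a standard
#' coalescent under the demography.  Mutations drop on all branches at rate
#' `u` per bp per generation.
#'
#' @param trajectory counts vector (origin to present) or a
#'   single-trajectory `trajectory_set`.
#' @param demography a [demographic_model()].
#' @param locus a [locus_params()]; `focal_pos` places the focal site within
#'   the simulated region of length `l`.
#' @param n number of derived-carrying haplotypes to sample.
#' @param n_ancestral additional haplotypes sampled from the ancestral class
#'   (used for cohort-style fixtures).
#' @param seed integer seed or `NULL`.
#' @return a `haplotype_set`: `positions` (bp, floored, within `[0, l]`),
#'   `genotypes` (0/1 matrix, one row per haplotype, derived rows first),
#'   `derived` (logical), `focal_pos`, `u`, `r`, `l`.
#' @export
simulate_haplotypes <- function(trajectory, demography, locus, n,
                                n_ancestral = 0, seed = NULL) {
  cc <- if (inherits(trajectory, "trajectory_set")) trajectory$counts[[1]] else
    as.integer(trajectory)
  if (length(cc) < 1 || cc[1] != 1)
    stop("trajectory must start at copy number 1 at its origin")
  if (any(cc < 1)) stop("trajectory counts must stay positive until the present")
  if (n > cc[length(cc)])
    stop("n exceeds the derived copy number at the present (",
         cc[length(cc)], ")")
  if (n + n_ancestral > 128)
    stop("at most 128 haplotypes can be sampled jointly")
  twoN <- 2 * pop_size_at(demography, rev(seq_along(cc)) - 1)
  if (any(cc >= twoN))
    stop("trajectory and demography are inconsistent: count >= 2N")
  .hd_set_seed(seed)
  bp <- .demog_bp(demography)
  res <- cpp_simulate_haplotypes(cc, bp$sizes,
                                 pmin(bp$ends, .Machine$double.xmax),
                                 as.integer(n), as.integer(n_ancestral),
                                 locus$u, locus$r, locus$l, locus$focal_pos,
                                 .coal_time_cap(demography))
  pos <- floor(res$positions)
  structure(list(positions = pos, genotypes = res$genotypes,
                 derived = c(rep(TRUE, n), rep(FALSE, n_ancestral)),
                 focal_pos = locus$focal_pos, u = locus$u, r = locus$r,
                 l = locus$l),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set: %d haplotypes (%d derived), %d segregating sites\n",
              nrow(x$genotypes), sum(x$derived), ncol(x$genotypes)))
  invisible(x)
}

#' Per-window IBS probabilities for one trajectory
#'
#' Runs [simulate_haplotypes()] `reps` times, computes all `choose(n, 2)`
#' first-difference windows per replicate in the direction(s) implied by the
#' focal position (both directions when the focal site is interior to the
#' region, downstream only when it sits at the left end), and returns the
#' pooled empirical probability vector over the `M` windows.
#'
#' @inheritParams simulate_haplotypes
#' @param windows a [window_scheme()].
#' @param reps haplotype sets per trajectory (the Monte-Carlo budget).
#' @return numeric probability vector of length `M` (sums to 1).
#' @export
window_probabilities <- function(trajectory, demography, locus, n, windows,
                                 reps = 100, seed = NULL) {
  stopifnot(inherits(windows, "window_scheme"), reps >= 1)
  cc <- if (inherits(trajectory, "trajectory_set")) trajectory$counts[[1]] else
    as.integer(trajectory)
  .hd_set_seed(seed)
  directions <- if (locus$focal_pos > 0 && locus$focal_pos < locus$l) 2L else 1L
  counts <- .window_counts_batch(list(cc), demography, locus, n, windows,
                                 reps, directions)
  as.numeric(counts[1, ] / sum(counts[1, ]))
}

# pooled window counts for a list of trajectories (internal batch path);
# directions = 1 puts the focal allele at the left end of a one-sided region
.window_counts_batch <- function(counts_list, demography, locus, n, windows,
                                 reps, directions = 1L) {
  bp <- .demog_bp(demography)
  cap <- .coal_time_cap(demography)
  if (directions == 1L) {
    cpp_window_counts_batch(counts_list, bp$sizes,
                            pmin(bp$ends, .Machine$double.xmax),
                            as.integer(n), locus$u, locus$r,
                            windows$boundaries, as.integer(reps), cap)
  } else {
    # midpoint variant: reuse the per-pair path rep times and pool
    M <- windows$M
    out <- matrix(0, length(counts_list), M)
    for (rep in seq_len(reps)) {
      pw <- cpp_ibs_pair_windows(counts_list, bp$sizes,
                                 pmin(bp$ends, .Machine$double.xmax),
                                 as.integer(n), locus$u, locus$r,
                                 windows$boundaries, 2L, cap)
      for (i in seq_along(pw))
        out[i, ] <- out[i, ] + tabulate(as.integer(pw[[i]]), nbins = M)
    }
    out
  }
}
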