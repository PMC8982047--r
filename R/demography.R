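#' Piecewise-constant demographic model
#'
#' A demographic history is an ordered sequence of epochs of constant diploid
#' population size, most ancient first, with the last epoch ending at the
#' present.  The most ancient epoch is open-ended: forward simulations run it
#' for a configurable burn-in before any more recent epoch starts.
#'
#' @param sizes diploid effective population sizes, most ancient epoch first.
#' @param durations epoch durations in generations, aligned with `sizes`.
#'   The first (most ancient) entry may be `Inf` (open-ended); all other
#'   durations must be at least 1.
#' @param label free-text label for the model.
#' @return an object of class `demographic_model`.
#' @examples
#' constant_model(10000)
#' demographic_model(c(5000, 50000), c(Inf, 100), "expansion")
#' @export
demographic_model <- function(sizes, durations = rep(Inf, length(sizes)),
                              label = "model") {
  stopifnot(length(sizes) == length(durations), length(sizes) >= 1)
  sizes <- round(sizes)  # diploid individuals; 2N must be integral
  if (any(sizes < 2)) stop("all epoch sizes must be >= 2")
  if (length(sizes) > 1 && any(durations[-1] < 1))
    stop("all epoch durations after the most ancient must be >= 1 generation")
  if (length(sizes) > 1 && any(!is.finite(durations[-1])))
    stop("only the most ancient epoch may be open-ended")
  structure(list(sizes = as.numeric(sizes),
                 durations = as.numeric(durations),
                 label = as.character(label)[1]),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @param N diploid size of the single epoch.
#' @export
constant_model <- function(N, label = sprintf("constant-N%d", round(N))) {
  demographic_model(N, Inf, label)
}

#' @rdname demographic_model
#' @param n_ancient,n_recent diploid sizes before and after the expansion.
#' @param t_expansion generations before present at which the size changed.
#' @export
expansion_model <- function(n_ancient, n_recent, t_expansion,
                            label = sprintf("expansion-%d-%d-t%d",
                                            round(n_ancient), round(n_recent),
                                            round(t_expansion))) {
  demographic_model(c(n_ancient, n_recent), c(Inf, t_expansion), label)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", x$label, "\n")
  for (i in seq_along(x$sizes))
    cat(sprintf("  epoch %d: N = %g, duration = %g generations\n",
                i, x$sizes[i], x$durations[i]))
  invisible(x)
}

#' Most ancient epoch size
#'
#' The diploid size N of the most ancient epoch defines the population-scaled
#' parameters 4Ns and theta.
#' @param demography a [demographic_model()].
#' @export
ancient_size <- function(demography) demography$sizes[1]

#' Diploid size at a time before the present
#' @param demography a [demographic_model()].
#' @param t generations before the present (0 = present).
#' @return diploid size(s) at `t`.
#' @export
pop_size_at <- function(demography, t) {
  bp <- .demog_bp(demography)
  vapply(t, function(tt) {
    i <- findInterval(tt, c(0, bp$ends), rightmost.closed = FALSE)
    bp$sizes[min(i, length(bp$sizes))]
  }, numeric(1))
}

# recent-first sizes and cumulative epoch end times (gens before present)
.demog_bp <- function(demography) {
  k <- length(demography$sizes)
  sizes <- rev(demography$sizes)
  durs <- rev(demography$durations)
  ends <- cumsum(durs)
  ends[k] <- Inf
  list(sizes = sizes, ends = ends)
}

# per-generation forward size vector over a simulation horizon; the most
# ancient epoch absorbs whatever the fixed recent epochs do not cover
.demog_fwd <- function(demography, horizon) {
  recent <- if (length(demography$sizes) > 1) sum(demography$durations[-1]) else 0
  anc <- horizon - recent
  if (anc < 1)
    stop("simulation horizon shorter than the fixed recent epochs (",
         recent, " generations)")
  rep(demography$sizes, times = c(anc, if (length(demography$sizes) > 1)
    demography$durations[-1] else NULL))
}

#' Selection parameters
#'
#' The population-scaled selection coefficient gamma = 4Ns is defined with
#' respect to N, the diploid size of the most ancient epoch; the
#' per-generation coefficient s = gamma / (4N) is constant across epochs, so
#' the effective scaled coefficient changes when the population size changes.
#' Negative gamma denotes deleterious alleles.
#'
#' @param gamma dimensionless 4Ns.
#' @param dominance dominance coefficient h in \[0, 1\] (0.5 = codominant).
#' @export
selection_params <- function(gamma, dominance = 0.5) {
  stopifnot(is.finite(gamma), dominance >= 0, dominance <= 1)
  structure(list(gamma = gamma, dominance = dominance),
            class = "selection_params")
}

.as_selection <- function(x) {
  if (inherits(x, "selection_params")) x else selection_params(x)
}

#' Sampling configuration
#'
#' @param S number of sampled chromosomes.
#' @param f target sample frequency of the derived allele.
#' @param tolerance half-width of the accepted frequency band around `f`.
#' @param n number of derived-allele haplotypes used for IBS lengths
#'   (default: `round(f * S)`).
#' @param A number of independent focal loci.
#' @export
sample_config <- function(S, f, tolerance = 0, n = round(f * S), A = 1) {
  stopifnot(S >= 2, f > 0, f < 1, tolerance >= 0)
  if (round(f * S) < 2) stop("round(f * S) must be >= 2")
  band <- .band_counts(S, f, tolerance)
  if (n > band[2])
    stop("n exceeds the largest sample count in the accepted band (", band[2], ")")
  structure(list(S = as.integer(S), f = f, tolerance = tolerance,
                 n = as.integer(n), A = as.integer(A)),
            class = "sample_config")
}

# accepted present-day sample counts [lo, hi]
.band_counts <- function(S, f, tolerance) {
  lo <- ceiling((f - tolerance) * S - 1e-9)
  hi <- floor((f + tolerance) * S + 1e-9)
  c(max(1L, as.integer(lo)), as.integer(hi))
}

#' Per-locus mutation and recombination parameters
#'
#' @param u per-base per-generation mutation rate.
#' @param r per-base per-generation recombination rate.
#' @param l region length in bp.
#' @param focal_pos bp coordinate of the focal (selected) site; defaults to
#'   the region midpoint so IBS lengths can be taken in both directions.
#' @export
locus_params <- function(u = 1.2e-8, r = 1.0e-8, l = 5e5, focal_pos = l / 2) {
  stopifnot(u >= 0, r >= 0, l > 0, focal_pos >= 0, focal_pos <= l)
  structure(list(u = u, r = r, l = l, focal_pos = focal_pos),
            class = "locus_params")
}

#' Population-scaled locus rates
#'
#' theta = 4*N*u*l and rho = 4*N*r*l, with N the most ancient epoch size.
#' @param demography a [demographic_model()].
#' @param locus a [locus_params()].
#' @export
locus_theta <- function(demography, locus) 4 * ancient_size(demography) * locus$u * locus$l

#' @rdname locus_theta
#' @export
locus_rho <- function(demography, locus) 4 * ancient_size(demography) * locus$r * locus$l

#' Rescale a model for faster simulation
#'
#' Divides population sizes by `factor` while multiplying the per-generation
#' mutation rate, recombination rate and selection coefficient by the same
#' factor, leaving the population-scaled parameters 4Ns, theta = 4Nul and
#' rho = 4Nrl unchanged (up to rounding of the sizes).  Epoch durations are
#' not changed.
#'
#' @param demography a [demographic_model()].
#' @param selection a [selection_params()] (gamma is scale-free and kept).
#' @param locus a [locus_params()].
#' @param factor rescaling factor (>= 1).
#' @return list with rescaled `demography`, `selection`, `locus`.
#' @export
rescale_model <- function(demography, selection, locus, factor) {
  stopifnot(factor >= 1)
  sizes <- round(demography$sizes / factor)
  if (any(sizes < 2)) stop("rescaling factor produces an epoch size < 2")
  dem <- demographic_model(sizes, demography$durations,
                           paste0(demography$label, sprintf(" (scaled 1/%g)", factor)))
  loc <- locus_params(u = locus$u * factor, r = locus$r * factor, l = locus$l,
                      focal_pos = locus$focal_pos)
  list(demography = dem, selection = selection, locus = loc)
}
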