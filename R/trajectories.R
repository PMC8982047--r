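#' Forward-in-time simulation under the Poisson Random Field model
#'
#' Each generation receives `Poisson(theta_g / 2)` new unlinked mutations at
#' copy number 1, where `theta_g` scales with the population size of that
#' generation (`theta` refers to the most ancient epoch).  Copy numbers then
#' follow Wright-Fisher binomial sampling around the selection-adjusted
#' expected frequency
#' `x' = x (1 + s h + s (1 - h) x) / (1 + 2 s h x (1 - x) + s x^2)`.
#' Only mutations still segregating at the final generation are returned,
#' with their full per-generation copy-number histories.
#'
#' @param demography a [demographic_model()].
#' @param selection a [selection_params()] or a bare 4Ns value.
#' @param theta population mutation rate of the most ancient epoch.
#' @param generations total generations simulated; must cover the default
#'   burn-in of `burn_in` generations plus all recent epochs.
#' @param burn_in minimum burn-in (default `10 * N` of the most ancient
#'   epoch, enough to reach mutation-selection balance).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `trajectory_set`: list of per-generation copy-count vectors
#'   (index 1 = generation of origin, count 1; last index = present).
#' @export
simulate_prf <- function(demography, selection, theta,
                         generations = NULL,
                         burn_in = 10 * ancient_size(demography),
                         seed = NULL) {
  selection <- .as_selection(selection)
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) || theta <= 0)
    stop("theta must be a single positive number")
  recent <- if (length(demography$sizes) > 1) sum(demography$durations[-1]) else 0
  if (is.null(generations)) generations <- burn_in + recent
  if (!is.finite(generations) || generations < burn_in + recent)
    stop("generations must be at least burn_in plus the recent epoch durations (",
         burn_in + recent, ")")
  .hd_set_seed(seed)
  sizes_fwd <- .demog_fwd(demography, generations)
  res <- cpp_simulate_prf(sizes_fwd, theta, ancient_size(demography),
                          selection$gamma, selection$dominance)
  structure(list(counts = res$counts, final_sample_count = NULL,
                 demography = demography, selection = selection,
                 theta = theta, generations = generations),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  gam <- if (!is.null(x$selection)) sprintf("4Ns = %g", x$selection$gamma)
         else "DFE-distributed 4Ns"
  cat(sprintf("Trajectory set: %d trajectories (%s, %s)\n",
              length(x$counts), gam, x$demography$label))
  if (!is.null(x$final_sample_count))
    cat(sprintf("  conditioned: sample counts %s\n",
                paste(range(x$final_sample_count), collapse = "-")))
  invisible(x)
}

#' @export
length.trajectory_set <- function(x) length(x$counts)

#' Condition trajectories on a present-day sample frequency
#'
#' For each trajectory a present-day sample count is drawn as
#' `Binomial(S, x_final)`; the trajectory is retained iff the count divided
#' by `S` falls within `f` plus or minus the tolerance.
#'
#' @param trajectories a `trajectory_set` from [simulate_prf()].
#' @param sample a [sample_config()].
#' @param seed integer seed or `NULL`.
#' @return the retained subset with `final_sample_count` recorded.
#' @export
condition_on_frequency <- function(trajectories, sample, seed = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(sample, "sample_config"))
  .hd_set_seed(seed)
  band <- .band_counts(sample$S, sample$f, sample$tolerance)
  n2_present <- 2 * pop_size_at(trajectories$demography, 0)
  xf <- vapply(trajectories$counts, function(cc) cc[length(cc)], numeric(1)) /
    n2_present
  k <- rbinom(length(xf), sample$S, xf)
  keep <- k >= band[1] & k <= band[2]
  if (!any(keep)) {
    stop(sprintf(
      "no accepted trajectories: 0 of %d within the frequency band (acceptance rate 0)",
      length(xf)))
  }
  out <- trajectories
  out$counts <- trajectories$counts[keep]
  out$final_sample_count <- as.integer(k[keep])
  out$sample <- sample
  out$acceptance_rate <- mean(keep)
  out
}

#' Rejection-sample trajectories conditioned at a sample frequency
#'
#' Draws independent conditioned trajectories directly: mutations arise at a
#' rate proportional to the population size, evolve under Wright-Fisher
#' dynamics with selection, and are retained when a binomial sample of `S`
#' chromosomes at the present carries the derived allele within the accepted
#' frequency band.  Under a constant size the stationarity of the mutation
#' influx is exploited, so every segregating generation of a simulated
#' allele is an exchangeable candidate present; under multi-epoch models the
#' present is the end of the final epoch.
#'
#' @inheritParams simulate_prf
#' @param sample a [sample_config()].
#' @param n_target number of accepted trajectories wanted.
#' @param max_alleles cap on the number of simulated mutations.
#' @return a conditioned `trajectory_set` with `final_sample_count`.
#' @export
sample_trajectories_at_frequency <- function(demography, selection, sample,
                                             n_target,
                                             burn_in = 10 * ancient_size(demography),
                                             max_alleles = 5e7,
                                             seed = NULL) {
  selection <- .as_selection(selection)
  stopifnot(inherits(sample, "sample_config"), n_target >= 1)
  .hd_set_seed(seed)
  band <- .band_counts(sample$S, sample$f, sample$tolerance)
  if (length(demography$sizes) == 1) {
    res <- cpp_conditioned_constN(demography$sizes[1], selection$gamma,
                                  selection$dominance, sample$S,
                                  band[1], band[2], as.integer(n_target),
                                  max_alleles)
  } else {
    # boundary stationarity: the open-ended ancient epoch is at
    # mutation-selection balance where the recent epochs begin
    recent_sizes <- rep(demography$sizes[-1], times = demography$durations[-1])
    res <- cpp_conditioned_boundary(ancient_size(demography), recent_sizes,
                                    selection$gamma, selection$dominance,
                                    sample$S, band[1], band[2],
                                    as.integer(n_target), max_alleles)
  }
  if (length(res$counts) < n_target)
    stop(sprintf("no accepted trajectories: %d of %d after %g simulated alleles",
                 length(res$counts), n_target, res$alleles_tried))
  structure(list(counts = res$counts, final_sample_count = res$k,
                 demography = demography, selection = selection,
                 sample = sample, alleles_tried = res$alleles_tried),
            class = "trajectory_set")
}

#' Allele age
#'
#' The age of an allele is the number of generations it has existed,
#' i.e. the length of its copy-number trajectory.
#'
#' @param trajectory a single counts vector or a `trajectory_set`.
#' @return integer vector of ages in generations.
#' @export
allele_age <- function(trajectory) {
  if (inherits(trajectory, "trajectory_set"))
    return(vapply(trajectory$counts, length, integer(1)))
  length(trajectory)
}

#' Analytic distribution of the pairwise coalescent time T2
#'
#' For two lineages carrying the derived allele, the probability of
#' coalescing `t` generations before the present is
#' `(1 / c_t) * prod_{v < t} (1 - 1 / c_v)` where `c_t` is the derived copy
#' number `t` generations before the present.  Coalescence is certain by the
#' origin generation, where the copy number is 1.
#'
#' @param trajectory counts vector (origin to present) or a single-element
#'   `trajectory_set`.
#' @param demography unused (the distribution depends only on the derived
#'   copy-number trajectory); accepted for interface uniformity.
#' @return list with `t` (generations before present), `pmf`, `mean`, `sd`.
#' @export
t2_distribution <- function(trajectory, demography = NULL) {
  cc <- if (inherits(trajectory, "trajectory_set")) trajectory$counts[[1]] else trajectory
  age <- length(cc)
  if (any(cc < 1)) stop("trajectory counts must be >= 1 everywhere")
  if (age == 1) {
    return(list(t = 0, pmf = 1, mean = 0, sd = 0))
  }
  cbp <- rev(cc)            # index 1 = present
  tt <- seq_len(age - 1)    # generations before present
  ct <- cbp[tt + 1]         # copy number t generations before present
  pc <- 1 / ct
  surv <- cumprod(1 - pc)
  pmf <- pc * c(1, head(surv, -1))
  pmf[length(pmf)] <- pmf[length(pmf)] + surv[length(surv)]  # certain at origin
  m <- sum(tt * pmf)
  list(t = tt, pmf = pmf, mean = m, sd = sqrt(sum(tt^2 * pmf) - m^2))
}

#' Write / read trajectory sets as tab-separated text
#'
#' One row per generation with columns `trajectory_id`, `gen_before_present`,
#' `copies`, `pop_size`; metadata lines prefixed `#`.
#'
#' @param trajectories a `trajectory_set`.
#' @param path output file.
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  dem <- trajectories$demography
  hdr <- c(
    sprintf("# demography: %s", dem$label),
    sprintf("# sizes: %s", paste(dem$sizes, collapse = ",")),
    sprintf("# durations: %s", paste(dem$durations, collapse = ",")),
    sprintf("# gamma: %g", trajectories$selection$gamma),
    sprintf("# dominance: %g", trajectories$selection$dominance),
    if (!is.null(trajectories$theta)) sprintf("# theta: %g", trajectories$theta),
    if (!is.null(trajectories$final_sample_count))
      sprintf("# final_sample_count: %s",
              paste(trajectories$final_sample_count, collapse = ","))
  )
  rows <- lapply(seq_along(trajectories$counts), function(i) {
    cc <- trajectories$counts[[i]]
    age <- length(cc)
    tbp <- rev(seq_len(age)) - 1L
    data.frame(trajectory_id = i, gen_before_present = tbp, copies = cc,
               pop_size = pop_size_at(dem, tbp))
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(ln) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  sizes <- as.numeric(strsplit(get("sizes"), ",")[[1]])
  durations <- as.numeric(strsplit(get("durations"), ",")[[1]])
  dem <- demographic_model(sizes, durations, get("demography"))
  counts <- lapply(split(tab, tab$trajectory_id), function(d) {
    as.integer(d$copies[order(d$gen_before_present, decreasing = TRUE)])
  })
  names(counts) <- NULL
  fsc <- get("final_sample_count")
  structure(list(counts = counts,
                 final_sample_count = if (!is.null(fsc))
                   as.integer(strsplit(fsc, ",")[[1]]) else NULL,
                 demography = dem,
                 selection = selection_params(as.numeric(get("gamma")),
                                              as.numeric(get("dominance"))),
                 theta = if (!is.null(get("theta"))) as.numeric(get("theta"))),
            class = "trajectory_set")
}

#' Sample conditioned trajectories with DFE-distributed selection
#'
#' Joint rejection sampling of (4Ns, trajectory) pairs: every simulated
#' origination draws its deleterious 4Ns magnitude from a gamma DFE, so the
#' accepted set carries the distribution of fitness effects of variants at
#' the target frequency (the DFEf filtering arises from differential
#' acceptance).  Uses the same boundary-stationarity scheme as
#' [sample_trajectories_at_frequency()].
#'
#' @inheritParams sample_trajectories_at_frequency
#' @param psi `list(shape =, scale =)` gamma DFE over deleterious 4Ns.
#' @return a conditioned `trajectory_set` with a per-trajectory `gamma`
#'   vector.
#' @export
sample_trajectories_from_dfe <- function(demography, psi, sample, n_target,
                                         max_alleles = 5e7, seed = NULL) {
  stopifnot(inherits(sample, "sample_config"), n_target >= 1,
            is.numeric(psi$shape), is.numeric(psi$scale))
  .hd_set_seed(seed)
  band <- .band_counts(sample$S, sample$f, sample$tolerance)
  recent_sizes <- if (length(demography$sizes) > 1)
    rep(demography$sizes[-1], times = demography$durations[-1]) else numeric(0)
  res <- cpp_conditioned_dfe(ancient_size(demography), recent_sizes,
                             psi$shape, psi$scale, 0.5, sample$S,
                             band[1], band[2], as.integer(n_target),
                             max_alleles)
  if (length(res$counts) < n_target)
    stop(sprintf("no accepted trajectories: %d of %d after %g simulated alleles",
                 length(res$counts), n_target, res$alleles_tried))
  structure(list(counts = res$counts, final_sample_count = res$k,
                 gamma = res$gamma, demography = demography, psi = psi,
                 sample = sample, alleles_tried = res$alleles_tried),
            class = "trajectory_set")
}
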