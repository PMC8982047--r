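#' Discretized, tail-collapsed gamma distribution over 4Ns
#'
#' Probability mass at integer 4Ns values `g = 0..tau`:
#' `F(g + 0.5; alpha, beta) - F(max(g - 0.5, 0); alpha, beta)` for `g < tau`,
#' with the entire upper tail collapsed onto `tau`:
#' `1 - F(tau - 0.5; alpha, beta)`.
#'
#' @param alpha gamma shape (> 0).
#' @param beta gamma scale (> 0).
#' @param tau integer 4Ns threshold where the tail is collapsed.
#' @return numeric pmf over `0:tau` (sums to 1 exactly).
#' @export
discretized_gamma <- function(alpha, beta, tau) {
  stopifnot(alpha > 0, beta > 0, tau > 0)
  g <- 0:tau
  hi <- pgamma(g + 0.5, shape = alpha, scale = beta)
  lo <- pgamma(pmax(g - 0.5, 0), shape = alpha, scale = beta)
  if (any(!is.finite(hi)) || any(!is.finite(lo)))
    stop("non-finite gamma CDF evaluation")
  pmf <- hi - lo
  pmf[tau + 1] <- 1 - pgamma(tau - 0.5, shape = alpha, scale = beta)
  names(pmf) <- g
  pmf
}

# cache of discretized-gamma mixture matrices, keyed by the grid definition
.dfef_cache <- new.env(parent = emptyenv())

# rows ordered with the shape index varying fastest (matching matrix(ll, ...))
.dfef_gamma_matrix <- function(alpha_grid, beta_grid, tau) {
  key <- paste(c(alpha_grid, NA, beta_grid, NA, tau), collapse = ",")
  if (!is.null(.dfef_cache[[key]])) return(.dfef_cache[[key]])
  combos <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  Gm <- t(vapply(seq_len(nrow(combos)), function(i)
    discretized_gamma(combos$alpha[i], combos$beta[i], tau),
    numeric(tau + 1)))
  .dfef_cache[[key]] <- Gm
  Gm
}

#' Mean of the discretized gamma DFEf
#' @inheritParams discretized_gamma
#' @export
dfef_mean <- function(alpha, beta, tau) {
  sum((0:tau) * discretized_gamma(alpha, beta, tau))
}

#' Default shape and scale grids for the DFEf search
#'
#' Shape values span 0.03-0.9 (step 0.03); scale values span 3-210 (step 3)
#' and then 240-2310 (step 30).
#' @export
dfef_grids <- function() {
  list(alpha = seq(0.03, 0.9, by = 0.03),
       beta = c(seq(3, 210, by = 3), seq(240, 2310, by = 30)))
}

#' Estimate the DFEf by composite-likelihood grid search
#'
#' The per-record likelihood mixes the fixed-4Ns window probabilities over
#' the discretized gamma:
#' `sum_{g=0}^{tau} P(window | 4Ns = -g, f, D) * P(g; alpha, beta, tau)`.
#' The deleterious half-grid table must cover every integer magnitude in
#' `[0, tau]` with ESS at or above the threshold.
#'
#' @param data an `ibs_data` data frame or window-count vector.
#' @param table a `likelihood_table` whose grid is `0:-tau` (or `0:tau`
#'   magnitudes) in steps of 1.
#' @param alpha_grid,beta_grid candidate shape/scale values (defaults from
#'   [dfef_grids()]).
#' @param tau tail-collapse threshold (default 200).
#' @param ess_threshold required ESS at every table point.
#' @param eps zero-probability floor, as in [composite_loglik()].
#' @return a `dfef_params`: `alpha`, `beta`, `tau`, `pmf`, `mean_4Ns`,
#'   log-likelihood `surface` (alpha x beta matrix).
#' @export
estimate_dfef <- function(data, table, alpha_grid = dfef_grids()$alpha,
                          beta_grid = dfef_grids()$beta, tau = 200,
                          ess_threshold = 100, eps = NULL) {
  stopifnot(inherits(table, "likelihood_table"))
  mags <- abs(table$grid)
  need <- 0:tau
  pos <- match(need, mags)
  if (anyNA(pos))
    stop("table must cover every integer |4Ns| in [0, tau]; missing: ",
         paste(head(need[is.na(pos)]), collapse = ","))
  if (any(table$ess[pos] < ess_threshold))
    stop("table ESS below threshold at |4Ns| = ",
         paste(head(need[table$ess[pos] < ess_threshold]), collapse = ","))
  M <- ncol(table$pmf)
  cnt <- if (is.numeric(data) && is.null(dim(data))) as.numeric(data) else
    as.numeric(table(factor(data$window, levels = seq_len(M))))
  if (is.null(eps))
    eps <- 1 / (10 * table$meta$K * table$meta$reps * choose(table$meta$n, 2))
  P <- pmax(table$pmf[pos, , drop = FALSE], eps)  # (tau+1) x M
  Gm <- .dfef_gamma_matrix(alpha_grid, beta_grid, tau)  # combos x (tau+1)
  mix <- Gm %*% P                                       # combos x M
  ll <- as.numeric(log(mix) %*% cnt)
  surface <- matrix(ll, length(alpha_grid), length(beta_grid),
                    dimnames = list(alpha_grid, beta_grid))
  best <- which(surface == max(surface), arr.ind = TRUE)[1, ]
  alpha <- alpha_grid[best[1]]
  beta <- beta_grid[best[2]]
  structure(list(alpha = alpha, beta = beta, tau = tau,
                 pmf = discretized_gamma(alpha, beta, tau),
                 mean_4Ns = dfef_mean(alpha, beta, tau),
                 surface = surface),
            class = "dfef_params")
}

#' @export
print.dfef_params <- function(x, ...) {
  cat(sprintf("DFEf: shape = %g, scale = %g, tau = %d, mean |4Ns| = %.2f\n",
              x$alpha, x$beta, x$tau, x$mean_4Ns))
  invisible(x)
}

#' Selection-coefficient bins for the DFE of new mutations
#'
#' Endpoints `5 (i - 1)` and `5 i` for the first `b - 1` intervals, with an
#' open-ended final interval `[5 (b - 1), Inf)`.
#'
#' @param b number of bins.
#' @param lower optional custom lower endpoints (increasing, starting at 0),
#'   e.g. `c(0, 5, 50)` to aggregate reporting into the coarse intervals
#'   `[0,5)`, `[5,50)`, `[50,Inf)`.
#' @return a `dfe_bins_def`: lower endpoints and labels.
#' @export
dfe_bins_def <- function(b = 11, lower = NULL) {
  if (!is.null(lower)) {
    stopifnot(lower[1] == 0, all(diff(lower) > 0))
    b <- length(lower)
  } else {
    stopifnot(b >= 2)
    lower <- 5 * (seq_len(b) - 1)
  }
  labels <- c(sprintf("[%g,%g)", lower[-b], lower[-1]),
              sprintf("[%g,Inf)", lower[b]))
  structure(list(lower = lower, labels = labels, b = b), class = "dfe_bins_def")
}

# aggregate an integer-4Ns pmf (0..tau) into the 5-unit bins
.pmf_to_bins <- function(pmf, bins) {
  g <- as.numeric(names(pmf))
  idx <- findInterval(g, bins$lower)
  as.numeric(tapply(pmf, factor(idx, levels = seq_len(bins$b)), sum,
                    default = 0))
}

#' Monte-Carlo frequency conditionals linking the DFE and the DFEf
#'
#' Simulates mutations whose scaled selection coefficient magnitudes are
#' drawn from the DFE `psi` (a gamma over 4Ns, or a point mass), records for
#' every mutation its 4Ns bin and whether a binomial sample of `S`
#' chromosomes at the present finds it within the accepted frequency band,
#' and returns the count-based probabilities
#' `P(f | D)`, `P(s_j | f, D)` and `P(f | s_j, D)`.  All three derive from
#' the same counts, so the Bayes-rule reconstruction
#' `P(s_j) = P(s_j | f, D) P(f | D) / P(f | s_j, D)` is exact on them.
#'
#' @param psi DFE specification: `list(shape =, scale =)` for a gamma over
#'   deleterious 4Ns magnitudes, or `list(point =)` for a point mass.
#' @param demography a [demographic_model()].
#' @param sample a [sample_config()].
#' @param bins a [dfe_bins_def()].
#' @param n_sims number of simulated ancient-epoch alleles; each stands for
#'   `burn_in` originations, and recent-epoch originations are interleaved
#'   at their correct relative rate.
#' @param burn_in ancient origination horizon (default `10 N`); it cancels
#'   in the Bayes'-rule conversion, which uses ratios of the same counts.
#' @param dominance dominance coefficient.
#' @param seed integer seed or `NULL`.
#' @return a `frequency_conditionals` object.
#' @export
estimate_frequency_conditionals <- function(psi, demography, sample, bins,
                                            n_sims = 1e5,
                                            burn_in = 10 * ancient_size(demography),
                                            dominance = 0.5, seed = NULL) {
  stopifnot(inherits(sample, "sample_config"), inherits(bins, "dfe_bins_def"))
  .hd_set_seed(seed)
  band <- .band_counts(sample$S, sample$f, sample$tolerance)
  recent_sizes <- if (length(demography$sizes) > 1)
    rep(demography$sizes[-1], times = demography$durations[-1]) else numeric(0)
  point <- if (!is.null(psi$point)) psi$point else NA_real_
  res <- cpp_freq_conditionals(ancient_size(demography), recent_sizes,
                               burn_in, dominance,
                               sample$S, band[1], band[2],
                               if (is.na(point)) psi$shape else 1,
                               if (is.na(point)) psi$scale else 1,
                               point, bins$lower, n_sims)
  n_total <- res$n_total
  n_at_f <- res$n_at_f
  if (sum(n_at_f) == 0)
    stop("no simulated mutations at the target frequency; increase n_mut")
  p_f_given_sj <- ifelse(n_total > 0, n_at_f / n_total, NA_real_)
  structure(list(p_f = sum(n_at_f) / res$n_mut,
                 p_sj_given_f = n_at_f / sum(n_at_f),
                 p_f_given_sj = p_f_given_sj,
                 p_sj = n_total / res$n_mut,
                 counts = list(n_total = n_total, n_at_f = n_at_f,
                               n_mut = res$n_mut),
                 mean_4Ns_at_f = res$sum_4ns_at_f / sum(n_at_f),
                 bins = bins),
            class = "frequency_conditionals")
}

#' Convert a DFEf into the DFE of new mutations
#'
#' Bayes' rule per bin:
#' `P(s_j) = P(s_j | f, D) * P(f | D) / P(f | s_j, D)`, renormalized to sum
#' to 1 (Monte-Carlo noise breaks exact normalization); bins where
#' renormalization moved more than 1% of the total mass are flagged.
#'
#' @param dfef_bins probabilities `P(s_j | f, D)` per bin (e.g. the
#'   estimated DFEf aggregated with the bins definition), or a
#'   `dfef_params` object.
#' @param conditionals a `frequency_conditionals` object.
#' @return a `dfe_bins` object: `p` (bin probabilities), `bins`,
#'   `renorm_shift`, `flagged`.
#' @export
convert_dfef_to_dfe <- function(dfef_bins, conditionals) {
  stopifnot(inherits(conditionals, "frequency_conditionals"))
  bins <- conditionals$bins
  if (inherits(dfef_bins, "dfef_params"))
    dfef_bins <- .pmf_to_bins(dfef_bins$pmf, bins)
  stopifnot(length(dfef_bins) == bins$b)
  num <- dfef_bins * conditionals$p_f
  den <- conditionals$p_f_given_sj
  bad <- dfef_bins > 0 & (is.na(den) | den == 0)
  if (any(bad))
    stop("zero denominator P(f | s_j, D) with nonzero DFEf mass in bins: ",
         paste(bins$labels[bad], collapse = ", "))
  raw <- ifelse(dfef_bins > 0, num / den, 0)
  p <- raw / sum(raw)
  shift <- abs(p - raw)
  structure(list(p = p, bins = bins, raw = raw,
                 renorm_shift = sum(abs(p - raw)) / 2,
                 flagged = bins$labels[shift > 0.01]),
            class = "dfe_bins")
}

#' @export
print.dfe_bins <- function(x, ...) {
  cat("DFE over 4Ns bins:\n")
  for (i in seq_along(x$p))
    cat(sprintf("  %-12s %.4f\n", x$bins$labels[i], x$p[i]))
  invisible(x)
}

#' Locus-level bootstrap
#'
#' Resamples loci (not individual IBS records) with replacement, keeping
#' each locus's full record block, re-runs the estimator on every
#' replicate, and returns percentile intervals.  Failed replicates are
#' dropped and counted; the run fails when more than 10% drop.
#'
#' @param data an `ibs_data` data frame.
#' @param estimator function taking an `ibs_data` and returning a numeric
#'   vector (possibly named).
#' @param B bootstrap replicates (default 100).
#' @param probs interval probabilities (default the 90% interval).
#' @param seed integer seed or `NULL`.
#' @return list with `replicates` (B x p matrix), `intervals`, `dropped`.
#' @export
bootstrap_loci <- function(data, estimator, B = 100, probs = c(0.05, 0.95),
                           seed = NULL) {
  ids <- unique(data$locus_id)
  if (length(ids) < 2) stop("bootstrap needs at least 2 loci")
  .hd_set_seed(seed)
  blocks <- split(seq_len(nrow(data)), data$locus_id)
  reps <- vector("list", B)
  dropped <- 0L
  for (b in seq_len(B)) {
    pick <- sample(as.character(ids), length(ids), replace = TRUE)
    idx <- unlist(blocks[pick], use.names = FALSE)
    boot <- data[idx, , drop = FALSE]
    # re-key resampled loci so duplicated draws stay distinct blocks
    boot$locus_id <- rep(seq_along(pick),
                         times = vapply(blocks[pick], length, integer(1)))
    for (at in c("n_derived", "locus_r", "locus_u"))
      attr(boot, at) <- setNames(attr(data, at)[pick],
                                 as.character(seq_along(pick)))
    attr(boot, "scheme") <- attr(data, "scheme")
    class(boot) <- class(data)
    est <- tryCatch(estimator(boot), error = function(e) NULL)
    if (is.null(est)) dropped <- dropped + 1L else reps[[b]] <- est
  }
  if (dropped > 0.1 * B)
    stop(sprintf("bootstrap failed: %d of %d replicates errored", dropped, B))
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  list(replicates = mat,
       intervals = apply(mat, 2, quantile, probs = probs),
       dropped = dropped)
}
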