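#' Configuration for rejection-ABC demographic inference
#'
#' Priors are log-uniform for population sizes and uniform for epoch times.
#'
#' @param model `"constant"` (parameter `N`) or `"expansion"` (parameters
#'   `n_ancient`, `n_recent`, `t_expansion`).
#' @param priors named list of `c(lower, upper)` ranges for every model
#'   parameter.
#' @param n_draws prior draws.
#' @param acceptance_quantile fraction of draws accepted (in `(0, 0.5]`).
#' @param A loci simulated per draw.
#' @param reps haplotype pairs per locus in the simulated summaries.
#' @export
abc_config <- function(model = c("constant", "expansion"), priors, n_draws,
                       acceptance_quantile = 0.05, A = 50, reps = 10) {
  model <- match.arg(model)
  need <- if (model == "constant") "N" else
    c("n_ancient", "n_recent", "t_expansion")
  if (!all(need %in% names(priors)))
    stop("priors must name: ", paste(need, collapse = ", "))
  for (p in need) {
    rg <- priors[[p]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] <= 0 || rg[2] < rg[1])
      stop("improper prior range for ", p)
  }
  stopifnot(acceptance_quantile > 0, acceptance_quantile <= 0.5, n_draws >= 2)
  structure(list(model = model, priors = priors[need],
                 n_draws = as.integer(n_draws),
                 acceptance_quantile = acceptance_quantile,
                 A = as.integer(A), reps = reps),
            class = "abc_config")
}

.abc_model <- function(config, params) {
  if (config$model == "constant") constant_model(params[["N"]])
  else expansion_model(params[["n_ancient"]], params[["n_recent"]],
                       params[["t_expansion"]])
}

.abc_draw_prior <- function(config) {
  vapply(names(config$priors), function(p) {
    rg <- config$priors[[p]]
    if (p == "t_expansion") runif(1, rg[1], rg[2])
    else exp(runif(1, log(rg[1]), log(rg[2])))  # log-uniform for sizes
  }, numeric(1))
}

#' Neutral IBS window summaries under a candidate demography
#'
#' Simulates `A` neutral (4Ns = 0) loci conditioned at the target sample
#' frequency by rejection sampling, computes the pooled IBS window
#' proportions over pairs and both directions, and returns the length-M
#' summary vector.  Pairs are simulated independently (`reps` per locus);
#' under the binomial sampling convention the pooled pairwise window
#' proportions match those of jointly simulated haplotype sets.
#'
#' @param params named parameter vector instantiating the model family
#'   (e.g. `c(N = 1000)`), or a [demographic_model()] directly.
#' @param sample a [sample_config()].
#' @param locus a [locus_params()].
#' @param scheme a [window_scheme()].
#' @param A number of neutral loci.
#' @param reps haplotype pairs per locus.
#' @param model model family for named parameters (`"constant"` or
#'   `"expansion"`).
#' @param seed integer seed or `NULL`.
#' @export
neutral_summaries <- function(params, sample, locus, scheme, A,
                              reps = 10, model = "constant", seed = NULL) {
  .hd_set_seed(seed)
  dem <- if (inherits(params, "demographic_model")) params else
    .abc_model(list(model = model), as.list(params))
  ts <- sample_trajectories_at_frequency(dem, selection_params(0), sample,
                                         n_target = A)
  cnt <- .window_counts_batch(ts$counts, dem, locus, 2, scheme,
                              reps = reps, directions = 2L)
  tot <- colSums(cnt)
  tot / sum(tot)
}

#' Rejection ABC over a demographic model family
#'
#' Draws parameters from the priors, simulates the neutral window summary
#' under each draw, measures the Euclidean distance to the observed summary,
#' and accepts the closest quantile.
#'
#' @param observed_summary length-M window proportion vector (same scheme as
#'   the simulations).
#' @param config an [abc_config()].
#' @param sample a [sample_config()].
#' @param locus a [locus_params()].
#' @param scheme a [window_scheme()].
#' @param seed integer seed or `NULL`.
#' @return an `abc_posterior`: `draws` (with distances and acceptance
#'   flags), `accepted`, `point_estimates` (posterior medians).
#' @export
abc_reject <- function(observed_summary, config, sample, locus, scheme,
                       seed = NULL) {
  stopifnot(inherits(config, "abc_config"))
  if (length(observed_summary) != scheme$M)
    stop("observed summary length does not match the window scheme")
  .hd_set_seed(seed)
  np <- length(config$priors)
  draws <- vapply(seq_len(config$n_draws),
                  function(i) .abc_draw_prior(config), numeric(np))
  draws <- t(matrix(draws, nrow = np))
  colnames(draws) <- names(config$priors)
  sims <- matrix(NA_real_, config$n_draws, scheme$M)
  for (i in seq_len(config$n_draws)) {
    dem <- .abc_model(config, as.list(draws[i, ]))
    sims[i, ] <- neutral_summaries(dem, sample, locus, scheme, config$A,
                                   reps = config$reps)
  }
  if (all(apply(sims, 2, function(x) diff(range(x)) == 0)))
    stop("degenerate simulated summaries: all draws identical")
  dist <- sqrt(rowSums((sims - matrix(observed_summary, config$n_draws,
                                      scheme$M, byrow = TRUE))^2))
  n_acc <- ceiling(config$acceptance_quantile * config$n_draws)
  acc <- rank(dist, ties.method = "first") <= n_acc
  out <- data.frame(draws, distance = dist, accepted = acc)
  structure(list(draws = out,
                 accepted = out[acc, , drop = FALSE],
                 point_estimates = apply(draws[acc, , drop = FALSE], 2, median),
                 config = config),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior (%s model): %d of %d draws accepted\n",
              x$config$model, nrow(x$accepted), nrow(x$draws)))
  for (p in names(x$point_estimates))
    cat(sprintf("  %s: median %.4g, 5-95%% [%.4g, %.4g]\n", p,
                x$point_estimates[p],
                quantile(x$accepted[[p]], 0.05),
                quantile(x$accepted[[p]], 0.95)))
  invisible(x)
}
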