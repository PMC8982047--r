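#' Build a per-4Ns likelihood table
#'
#' For each candidate 4Ns on the grid, `K` allele-frequency trajectories
#' ending at the target sample frequency are drawn from the backward
#' proposal shaped by that 4Ns, importance weights correct proposal to
#' target, and each trajectory's per-window IBS probability vector is
#' estimated from `reps` simulated haplotype sets of `n` carriers (focal
#' allele at the left end of a one-sided region, the table-building
#' convention).  The table entry is the self-normalized weighted average
#' probability vector together with its effective sample size.
#'
#' @param grid candidate 4Ns values (strictly increasing; default
#'   `seq(-200, 200, by = 5)`).
#' @param sample a [sample_config()].
#' @param demography a [demographic_model()].
#' @param locus a [locus_params()].
#' @param scheme a [window_scheme()].
#' @param K trajectories per grid point.
#' @param reps haplotype sets per trajectory.
#' @param seed integer seed or `NULL`.
#' @param method `"importance"` (default) or `"rejection"` (unweighted
#'   trajectories from the forward sampler; the slow oracle route).
#' @param dominance dominance coefficient used throughout.
#' @param n_sim haplotypes per coalescent replicate.  Because sampled
#'   chromosomes pick population copies with replacement, the marginal
#'   distribution of a pairwise IBS window does not depend on how many
#'   haplotypes are simulated jointly, so the table is built from
#'   independent pairs (`n_sim = 2`) by default; `reps` then counts pairs
#'   per trajectory.
#' @param smooth smooth each window's probability across the 4Ns grid by
#'   ESS-weighted local regression before renormalizing (default `TRUE`
#'   for grids with at least 8 points).  The underlying window
#'   probabilities vary smoothly in 4Ns, while the raw per-point
#'   Monte-Carlo noise is independent across grid points; smoothing removes
#'   most of that noise without touching the trajectory or haplotype
#'   budgets.
#' @return a `likelihood_table`: `grid`, `pmf` (grid x M matrix), `ess`,
#'   and metadata.
#' @export
build_table <- function(grid = seq(-200, 200, by = 5), sample, demography,
                        locus, scheme, K = 2000, reps = 20, seed = NULL,
                        method = c("importance", "rejection"),
                        dominance = 0.5, n_sim = 2,
                        smooth = length(grid) >= 8) {
  method <- match.arg(method)
  stopifnot(K >= 1, reps >= 1, all(diff(grid) > 0))
  .hd_set_seed(seed)
  M <- scheme$M
  pmf <- matrix(NA_real_, length(grid), M)
  essv <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    sel <- selection_params(grid[gi], dominance)
    if (method == "importance") {
      prop <- propose_trajectories(sample, demography, sel, K)
      iw <- tryCatch(importance_weights(prop, sel), error = function(e) NULL)
      if (is.null(iw)) { essv[gi] <- 0; next }
      counts <- .window_counts_batch(prop$counts, demography, locus,
                                     n_sim, scheme, reps)
      p <- counts / rowSums(counts)
      pmf[gi, ] <- as.numeric(crossprod(p, iw$w))
      essv[gi] <- iw$ess
    } else {
      ts <- sample_trajectories_at_frequency(demography, sel, sample, K)
      counts <- .window_counts_batch(ts$counts, demography, locus,
                                     n_sim, scheme, reps)
      p <- counts / rowSums(counts)
      pmf[gi, ] <- colMeans(p)
      essv[gi] <- K
    }
  }
  if (isTRUE(smooth)) pmf <- .smooth_table_pmf(grid, pmf, essv)
  structure(list(grid = grid, pmf = pmf, ess = essv,
                 meta = list(S = sample$S, f = sample$f,
                             tolerance = sample$tolerance, n = sample$n,
                             demography = demography$label,
                             sizes = demography$sizes,
                             durations = demography$durations,
                             u = locus$u, r = locus$r, l = locus$l,
                             boundaries = scheme$boundaries,
                             K = K, reps = reps, method = method,
                             dominance = dominance)),
            class = "likelihood_table")
}

# ESS-weighted local-regression smoothing of each window's probability over
# the 4Ns grid; rows are renormalized afterwards.  Rows with missing pmfs
# keep their NA (they stay ESS-masked downstream).
.smooth_table_pmf <- function(grid, pmf, ess) {
  ok <- stats::complete.cases(pmf) & ess > 0
  if (sum(ok) < 8) return(pmf)
  span <- min(0.75, max(0.25, 12 / sum(ok)))
  sm <- pmf
  for (j in seq_len(ncol(pmf))) {
    fit <- stats::loess(pmf[ok, j] ~ grid[ok], weights = ess[ok],
                        span = span, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    sm[ok, j] <- pmax(stats::predict(fit, grid[ok]), 1e-12)
  }
  sm[ok, ] <- sm[ok, , drop = FALSE] / rowSums(sm[ok, , drop = FALSE])
  sm
}

#' @export
print.likelihood_table <- function(x, ...) {
  cat(sprintf("Likelihood table: %d grid points in [%g, %g], M = %d windows\n",
              length(x$grid), min(x$grid), max(x$grid), ncol(x$pmf)))
  cat(sprintf("  ESS range: %.1f - %.1f (K = %d)\n", min(x$ess), max(x$ess),
              x$meta$K))
  invisible(x)
}

#' Composite log-likelihood surface over the 4Ns grid
#'
#' Each IBS record contributes the log of the table's window probability at
#' its window; records are treated as independent (composite likelihood).
#' Windows with zero estimated probability are floored at `eps` with a
#' warning.
#'
#' @param data an `ibs_data` data frame, or a length-M window-count vector.
#' @param table a `likelihood_table`.
#' @param eps floor for zero estimated probabilities (default
#'   `1 / (10 * K * reps * choose(n, 2))`).
#' @return numeric surface over `table$grid` (attribute `counts` keeps the
#'   window counts used).
#' @export
composite_loglik <- function(data, table, eps = NULL) {
  stopifnot(inherits(table, "likelihood_table"))
  M <- ncol(table$pmf)
  cnt <- if (is.numeric(data) && is.null(dim(data))) {
    if (length(data) != M) stop("window counts incompatible with the table scheme")
    as.numeric(data)
  } else {
    if (max(data$window) > M) stop("data windows incompatible with the table scheme")
    as.numeric(table(factor(data$window, levels = seq_len(M))))
  }
  if (is.null(eps))
    eps <- 1 / (10 * table$meta$K * table$meta$reps * choose(table$meta$n, 2))
  pm <- table$pmf
  zero_used <- any(pm[!is.na(pm)] < eps & rep(cnt > 0, each = nrow(pm))[!is.na(pm)])
  if (isTRUE(zero_used))
    warning("some observed windows had estimated probability below eps; floored")
  surface <- apply(pm, 1, function(p) {
    if (anyNA(p)) return(NA_real_)
    sum(cnt * log(pmax(p, eps)))
  })
  structure(surface, counts = cnt, grid = table$grid)
}

# tie-break toward neutrality: smallest |4Ns|, then negative before positive
.argmax_grid <- function(surface, grid) {
  ok <- which(!is.na(surface))
  if (!length(ok)) stop("all grid points are masked")
  best <- ok[surface[ok] >= max(surface[ok]) - 1e-9]
  best[order(abs(grid[best]), grid[best])][1]
}

#' Estimate 4Ns by ESS-gated grid search
#'
#' Sums composite log-likelihood surfaces across recombination-rate strata
#' (each locus is assigned to the stratum table whose `r` is nearest in log
#' space), masks grid points where any stratum's effective sample size is
#' below `ess_threshold`, and returns the argmax.
#'
#' @param data an `ibs_data` data frame.
#' @param tables a `likelihood_table` or list of tables (one per r-stratum).
#' @param ess_threshold grid points with ESS below this are masked
#'   (default 100).
#' @param eps passed to [composite_loglik()].
#' @return a `selection_estimate`: `mle_4Ns`, `surface`, `gated_out`,
#'   `ess_threshold`.
#' @export
estimate_4Ns <- function(data, tables, ess_threshold = 100, eps = NULL) {
  if (inherits(tables, "likelihood_table")) tables <- list(tables)
  grid <- tables[[1]]$grid
  for (tb in tables)
    if (!isTRUE(all.equal(tb$grid, grid)))
      stop("all stratum tables must share one 4Ns grid")
  # assign loci to strata by nearest log-r
  r_tab <- vapply(tables, function(tb) tb$meta$r, numeric(1))
  locus_r <- attr(data, "locus_r")
  if (length(tables) == 1) {
    strata <- list(data)
  } else {
    if (is.null(locus_r) || anyNA(locus_r))
      stop("per-locus recombination rates are required for stratified tables")
    lr <- log10(pmax(locus_r, 1e-300))
    lt <- log10(pmax(r_tab, 1e-300))
    assign_tab <- vapply(lr, function(x) which.min(abs(x - lt)), integer(1))
    names(assign_tab) <- names(locus_r)
    strata <- lapply(seq_along(tables), function(si) {
      ids <- as.integer(names(assign_tab)[assign_tab == si])
      data[data$locus_id %in% ids, , drop = FALSE]
    })
  }
  total <- rep(0, length(grid))
  masked <- rep(FALSE, length(grid))
  for (si in seq_along(tables)) {
    if (nrow(strata[[si]]) == 0) next
    surf <- composite_loglik(strata[[si]], tables[[si]], eps = eps)
    masked <- masked | is.na(surf) | tables[[si]]$ess < ess_threshold
    surf[is.na(surf)] <- 0
    total <- total + surf
  }
  total[masked] <- NA_real_
  idx <- .argmax_grid(total, grid)
  structure(list(mle_4Ns = grid[idx], surface = total, grid = grid,
                 gated_out = grid[masked], ess_threshold = ess_threshold),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf("4Ns estimate: %g (grid [%g, %g], %d of %d points ESS-masked)\n",
              x$mle_4Ns, min(x$grid), max(x$grid), length(x$gated_out),
              length(x$grid)))
  invisible(x)
}

#' Write / read a likelihood table as TSV with a metadata header
#' @param table a `likelihood_table`.
#' @param path file path.
#' @export
write_table_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- table$meta
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, paste(meta[[key]], collapse = ",")), con)
  tab <- data.frame(gamma = table$grid, ess = table$ess, table$pmf)
  names(tab) <- c("gamma", "ess", paste0("w", seq_len(ncol(table$pmf))))
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: ", "", kv)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    meta[[key]] <- if (anyNA(num)) val else num
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  structure(list(grid = tab$gamma,
                 pmf = as.matrix(tab[, grep("^w", names(tab)), drop = FALSE]),
                 ess = tab$ess, meta = meta),
            class = "likelihood_table")
}
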