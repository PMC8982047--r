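test_that("the discretized gamma is exactly normalized with a collapsed tail", {
  for (ab in list(c(0.184, 1599.313), c(0.5, 10), c(2, 3), c(0.03, 2310))) {
    pmf <- discretized_gamma(ab[1], ab[2], 200)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(pmf[["0"]], pgamma(0.5, ab[1], scale = ab[2]),
                 tolerance = 1e-12)
  }
  # independent oracle: numeric integration of the gamma density
  pmf <- discretized_gamma(0.184, 1599.313, 200)
  for (g in c(1, 5, 37, 150)) {
    oracle <- integrate(dgamma, g - 0.5, g + 0.5, shape = 0.184,
                        scale = 1599.313, rel.tol = 1e-10)$value
    expect_equal(pmf[[as.character(g)]], oracle, tolerance = 1e-8)
  }
  oracle_tail <- 1 - pgamma(199.5, 0.184, scale = 1599.313)
  expect_equal(pmf[["200"]], oracle_tail, tolerance = 1e-12)
  # raising tau never increases the mass below the old threshold
  p50 <- discretized_gamma(0.184, 1599.313, 50)
  p200 <- discretized_gamma(0.184, 1599.313, 200)
  expect_true(all(p200[1:50] <= p50[1:50] + 1e-15))
  expect_equal(p200[1:50], p50[1:50], tolerance = 1e-12)
})

test_that("a point-mass DFEf reduces the mixture to a fixed 4Ns", {
  tab <- local({
    grid <- -(0:30)
    M <- 6
    pmf <- t(vapply(abs(grid), function(g) {
      w <- dnorm(seq_len(M), mean = 3 + g / 20, sd = 1.5)
      w / sum(w)
    }, numeric(M)))
    structure(list(grid = grid, pmf = pmf, ess = rep(1000, 31),
                   meta = list(K = 1000, reps = 100, n = 2, r = 1e-8)),
              class = "likelihood_table")
  })
  cnt <- c(100, 80, 60, 40, 20, 50)
  # alpha huge with alpha * beta = g* concentrates all mass on g* = 12
  fit <- estimate_dfef(cnt, tab, alpha_grid = 1e4, beta_grid = 12 / 1e4,
                       tau = 30)
  expect_equal(fit$mean_4Ns, 12, tolerance = 1e-6)
  mix_ll <- max(fit$surface)
  fixed_ll <- composite_loglik(cnt, tab)[match(-12, tab$grid)]
  expect_equal(mix_ll, as.numeric(fixed_ll), tolerance = 1e-6)
})

test_that("the Bayes'-rule count identity is exact on shared counts", {
  dem <- constant_model(300)
  samp <- sample_config(S = 600, f = 0.02, tolerance = 0.005, n = 6)
  bins <- dfe_bins_def(3)
  cond <- estimate_frequency_conditionals(list(shape = 1, scale = 6), dem,
                                          samp, bins, n_sims = 3000,
                                          seed = 8)
  ok <- cond$counts$n_at_f > 0
  expect_true(all(ok))
  dfe <- convert_dfef_to_dfe(cond$p_sj_given_f, cond)
  expect_equal(dfe$raw[ok],
               (cond$counts$n_total / cond$counts$n_mut)[ok],
               tolerance = 1e-12)
  expect_equal(sum(dfe$p), 1, tolerance = 1e-12)
})

test_that("a point-mass DFE gives P(f | D) equal to P(f | s1, D)", {
  dem <- constant_model(300)
  samp <- sample_config(S = 600, f = 0.02, tolerance = 0.005, n = 6)
  bins <- dfe_bins_def(2)
  cond <- estimate_frequency_conditionals(list(point = 2), dem, samp, bins,
                                          n_sims = 2000, seed = 9)
  expect_equal(cond$p_f, cond$p_f_given_sj[1] *
                 cond$counts$n_total[1] / cond$counts$n_mut,
               tolerance = 1e-12)
  expect_equal(cond$p_sj_given_f, c(1, 0))
})

test_that("equal conditionals make the DFE equal the DFEf", {
  bins <- dfe_bins_def(4)
  cond <- structure(list(p_f = 0.01,
                         p_sj_given_f = c(0.5, 0.3, 0.15, 0.05),
                         p_f_given_sj = rep(0.01, 4),
                         counts = list(), bins = bins),
                    class = "frequency_conditionals")
  out <- convert_dfef_to_dfe(c(0.5, 0.3, 0.15, 0.05), cond)
  expect_equal(out$p, c(0.5, 0.3, 0.15, 0.05), tolerance = 1e-12)
  # zero denominator with mass is an error
  cond$p_f_given_sj[2] <- 0
  expect_error(convert_dfef_to_dfe(c(0.5, 0.3, 0.15, 0.05), cond),
               "denominator")
})

test_that("the locus bootstrap resamples blocks and reports intervals", {
  set.seed(11)
  mk_data <- function(A) {
    structure(
      data.frame(locus_id = rep(seq_len(A), each = 12),
                 direction = "down", pair = 1:12, length_bp = 1,
                 window = sample(1:6, 12 * A, TRUE)),
      n_derived = setNames(rep(4L, A), seq_len(A)),
      locus_r = setNames(rep(1e-8, A), seq_len(A)),
      locus_u = setNames(rep(1e-8, A), seq_len(A)),
      class = c("ibs_data", "data.frame"))
  }
  est_mean_win <- function(d) c(mw = mean(d$window))
  # with two identical loci any resample reproduces the point estimate
  d <- mk_data(2)
  d$window <- rep(3L, 24)
  b <- bootstrap_loci(d, est_mean_win, B = 5, seed = 1)
  expect_true(all(b$replicates[, "mw"] == 3))
  expect_error(bootstrap_loci(mk_data(1), est_mean_win, B = 2), "2 loci")
  # intervals widen as the number of loci shrinks
  wide <- bootstrap_loci(mk_data(8), est_mean_win, B = 60, seed = 2)
  narrow <- bootstrap_loci(mk_data(60), est_mean_win, B = 60, seed = 3)
  expect_gt(diff(wide$intervals[, "mw"]), diff(narrow$intervals[, "mw"]))
  # an estimator that always fails aborts the run
  expect_error(bootstrap_loci(mk_data(4), function(d) stop("boom"), B = 5),
               "replicates errored")
})
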