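# a deterministic table with smoothly separated window pmfs, for estimator
# unit tests that should not depend on simulation noise
hd_toy_table <- function(grid = seq(-200, 200, by = 10)) {
  M <- 6
  pmf <- t(vapply(grid, function(g) {
    w <- dnorm(seq_len(M), mean = 3 + abs(g) / 100, sd = 1.5)
    w / sum(w)
  }, numeric(M)))
  structure(list(grid = grid, pmf = pmf, ess = rep(1000, length(grid)),
                 meta = list(K = 1000, reps = 100, n = 2, r = 1e-8,
                             u = 1.2e-8, l = 5e5)),
            class = "likelihood_table")
}

test_that("the composite surface recovers the generating grid row", {
  tab <- hd_toy_table()
  set.seed(1)
  for (g in c(-50, 0, 100)) {
    cnt <- as.numeric(rmultinom(1, 50000, tab$pmf[match(g, tab$grid), ]))
    surf <- composite_loglik(cnt, tab)
    est <- tab$grid[haplodfe:::.argmax_grid(surf, tab$grid)]
    expect_equal(abs(est), abs(g))
  }
})

test_that("flat surfaces tie-break toward neutrality", {
  tab <- hd_toy_table()
  tab$pmf <- matrix(1 / 6, nrow(tab$pmf), 6)
  surf <- composite_loglik(c(10, 5, 3, 2, 1, 20), tab)
  expect_true(all(abs(surf - surf[1]) < 1e-9))
  expect_equal(tab$grid[haplodfe:::.argmax_grid(surf, tab$grid)], 0)
})

test_that("a single record contributes log pmf of its window", {
  tab <- hd_toy_table()
  surf <- composite_loglik(c(1, 0, 0, 0, 0, 0), tab)
  expect_equal(as.numeric(surf), log(tab$pmf[, 1]), tolerance = 1e-12)
})

test_that("zero-probability flooring leaves a clear argmax unchanged", {
  tab <- hd_toy_table()
  set.seed(2)
  cnt <- as.numeric(rmultinom(1, 20000, tab$pmf[match(-100, tab$grid), ]))
  e1 <- tab$grid[haplodfe:::.argmax_grid(composite_loglik(cnt, tab,
                                                          eps = 1e-8),
                                         tab$grid)]
  e2 <- tab$grid[haplodfe:::.argmax_grid(composite_loglik(cnt, tab,
                                                          eps = 1e-9),
                                         tab$grid)]
  expect_equal(e1, e2)
})

test_that("the default grid spans -200 to 200", {
  expect_equal(range(formals(build_table)$grid |> eval()), c(-200, 200))
})

test_that("an importance table is self-normalized and plausible", {
  cfg <- hd_const_scaled()
  sch <- window_scheme()
  tab <- build_table(c(-50, 0, 50), cfg$sample, cfg$demography, cfg$locus,
                     sch, K = 300, reps = 50, seed = 3)
  expect_equal(rowSums(tab$pmf), rep(1, 3), tolerance = 1e-9)
  expect_true(all(tab$ess >= 1 & tab$ess <= 300))
  # K = 1: the table pmf is exactly the single trajectory's pooled pmf
  tab1 <- build_table(0, cfg$sample, cfg$demography, cfg$locus, sch,
                      K = 1, reps = 30, seed = 4)
  expect_equal(sum(tab1$pmf), 1, tolerance = 1e-12)
  expect_equal(tab1$ess, 1)
})

test_that("ESS gating masks grid points and can exhaust the grid", {
  tab <- hd_toy_table(grid = c(-10, 0, 10))
  tab$ess <- c(1000, 50, 1000)
  d <- structure(data.frame(locus_id = 1, direction = "down", pair = 1,
                            length_bp = 10, window = 1L),
                 class = c("ibs_data", "data.frame"))
  est <- estimate_4Ns(d, tab, ess_threshold = 100)
  expect_true(0 %in% est$gated_out)
  expect_false(est$mle_4Ns == 0)
  expect_error(estimate_4Ns(d, tab, ess_threshold = 1e6), "masked")
})

test_that("recombination strata are assigned by nearest log-r", {
  grid <- c(-10, 0, 10)
  tab_lo <- hd_toy_table(grid)
  tab_lo$meta$r <- 1e-9
  tab_hi <- hd_toy_table(grid)
  tab_hi$meta$r <- 1e-7
  # make the high-r table prefer -10/+10 so assignment is observable
  tab_hi$pmf[2, ] <- rev(tab_hi$pmf[2, ])
  set.seed(7)
  d <- structure(
    data.frame(locus_id = rep(1:2, each = 40), direction = "down",
               pair = rep(1:40, 2), length_bp = 1,
               window = c(sample(1:6, 40, TRUE, tab_lo$pmf[2, ]),
                          sample(1:6, 40, TRUE, tab_hi$pmf[2, ]))),
    n_derived = c(`1` = 5L, `2` = 5L),
    locus_r = c(`1` = 2e-9, `2` = 5e-8),
    class = c("ibs_data", "data.frame"))
  est <- estimate_4Ns(d, list(tab_lo, tab_hi), ess_threshold = 0)
  expect_s3_class(est, "selection_estimate")
  # surfaces are invariant to record order
  d2 <- d[sample(nrow(d)), ]
  attributes(d2)[c("n_derived", "locus_r")] <-
    attributes(d)[c("n_derived", "locus_r")]
  class(d2) <- class(d)
  est2 <- estimate_4Ns(d2, list(tab_lo, tab_hi), ess_threshold = 0)
  expect_equal(est$surface, est2$surface)
})
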