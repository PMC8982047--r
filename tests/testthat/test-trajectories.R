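test_that("the mutation influx is Poisson with mean theta / 2", {
  set.seed(1)
  # a single-generation run leaves no time for loss: every injected mutation
  # is still segregating, so the count is the raw influx
  n_new <- replicate(60, length(simulate_prf(constant_model(200), 0,
                                             theta = 1000, generations = 1,
                                             burn_in = 1)))
  expect_gt(mean(n_new), 500 - 4 * sqrt(500 / 60))
  expect_lt(mean(n_new), 500 + 4 * sqrt(500 / 60))
  expect_error(simulate_prf(constant_model(200), 0, theta = -1), "theta")
  expect_error(simulate_prf(constant_model(200), 0, theta = 10,
                            generations = 10, burn_in = 100), "burn_in")
})

test_that("neutral segregating variants recover the 1/i frequency spectrum", {
  set.seed(7)
  ts <- simulate_prf(constant_model(200), 0, theta = 40, generations = 4000)
  pkg_counts <- vapply(ts$counts, function(cc) cc[length(cc)], numeric(1))
  # independent brute-force Wright-Fisher oracle at the same settings
  oracle_counts <- local({
    alive <- integer(0)
    for (g in 1:4000) {
      if (length(alive)) {
        alive <- hd_wf_step(alive, 400, 0, 200)
        alive <- alive[alive > 0 & alive < 400]
      }
      alive <- c(alive, rep(1L, rpois(1, 20)))
    }
    alive
  })
  brk <- c(0.5, 1.5, 3.5, 7.5, 15.5, 31.5, 400)
  tab <- rbind(table(cut(pkg_counts, brk)), table(cut(oracle_counts, brk)))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)
  # and the shape is ~ 1/i: twice as many singletons as doubletons, roughly
  expect_gt(sum(pkg_counts == 1) / sum(pkg_counts == 2), 1.4)
})

test_that("conditioning on the sample frequency respects the band", {
  dem <- constant_model(500)
  mk <- function(counts) structure(list(counts = counts, demography = dem),
                                   class = "trajectory_set")
  set.seed(2)
  ts <- mk(replicate(4000, c(1L, 10L), simplify = FALSE))  # x_final = 0.01
  cond <- condition_on_frequency(ts, sample_config(4000, 0.01, 0, n = 40))
  expect_true(all(cond$final_sample_count == 40L))
  cond2 <- condition_on_frequency(ts, sample_config(7242, 0.01, 0.0005, n = 72))
  expect_true(all(cond2$final_sample_count %in% 69:76))
  # an allele at a hopeless frequency is never accepted
  lost <- mk(replicate(50, c(1L, 1L), simplify = FALSE))   # x_final = 0.001
  expect_error(
    condition_on_frequency(lost, sample_config(100, 0.5, 0, n = 50)),
    "no accepted")
})

test_that("allele ages: base case, sign symmetry, closed form", {
  expect_equal(allele_age(c(1L)), 1L)
  samp <- sample_config(S = 2000, f = 0.01, tolerance = 0, n = 4)
  ts_neg <- sample_trajectories_at_frequency(hd_const(1000), -100, samp,
                                             1500, seed = 31)
  ts_pos <- sample_trajectories_at_frequency(hd_const(1000), +100, samp,
                                             1500, seed = 32)
  # under a constant size, +|4Ns| and -|4Ns| alleles at the same frequency
  # have indistinguishable age distributions
  ks <- suppressWarnings(ks.test(allele_age(ts_neg), allele_age(ts_pos)))
  expect_gt(ks$p.value, 0.01)
  # and strong selection of either sign makes alleles younger than neutral
  ts_neu <- sample_trajectories_at_frequency(hd_const(1000), 0, samp,
                                             1500, seed = 33)
  expect_gt(mean(allele_age(ts_neu)), mean(allele_age(ts_neg)))
  expect_gt(mean(allele_age(ts_neu)), mean(allele_age(ts_pos)))
  # neutral mean age approximates -4N (x/(1-x)) log(x)
  x <- 0.01
  closed <- -4 * 1000 * (x / (1 - x)) * log(x)
  ages <- allele_age(sample_trajectories_at_frequency(hd_const(1000), 0,
                                                      samp, 12000, seed = 34))
  expect_lt(abs(mean(ages) - closed) / closed, 0.12)
})

test_that("the analytic T2 distribution matches its structure and an oracle", {
  # two copies for T generations: geometric with forced coalescence at origin
  tr <- c(1L, rep(2L, 10L))
  t2 <- t2_distribution(tr)
  expect_equal(sum(t2$pmf), 1, tolerance = 1e-12)
  expect_equal(t2$pmf[1:9], 0.5^(1:9), tolerance = 1e-12)
  expect_equal(t2$pmf[10], 0.5^9, tolerance = 1e-12)
  expect_lte(max(t2$t), length(tr))
  # pmf sums to one for arbitrary conditioned trajectories
  samp <- sample_config(S = 2000, f = 0.01, tolerance = 0, n = 4)
  ts <- sample_trajectories_at_frequency(hd_const(1000), -50, samp, 30,
                                         seed = 5)
  sums <- vapply(ts$counts, function(cc) sum(t2_distribution(cc)$pmf),
                 numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  # two-lineage backward-simulation oracle on one fixed trajectory
  cc <- ts$counts[[which.max(allele_age(ts))]]
  cbp <- rev(cc)
  set.seed(9)
  draws <- replicate(10000, {
    t <- 1L
    while (t < length(cbp) && runif(1) >= 1 / cbp[t + 1]) t <- t + 1L
    t
  })
  t2a <- t2_distribution(cc)
  brk <- unique(quantile(draws, seq(0, 1, 0.2)))
  emp <- as.numeric(table(cut(draws, c(0, brk[-1]), include.lowest = TRUE)))
  ana <- vapply(seq_along(emp), function(i) {
    lo <- c(0, brk[-1])[i]
    hi <- c(0, brk[-1])[i + 1]
    sum(t2a$pmf[t2a$t > lo & t2a$t <= hi]) * 10000
  }, numeric(1))
  se <- sqrt(pmax(ana, 1))
  expect_true(all(abs(emp - ana) < 3.5 * se + 3))
})

test_that("trajectory sets round-trip through tab-separated text", {
  samp <- sample_config(S = 1000, f = 0.02, tolerance = 0, n = 4)
  ts <- sample_trajectories_at_frequency(hd_const(300), -20, samp, 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(ts, path)
  ts2 <- read_trajectories(path)
  expect_equal(lapply(ts2$counts, as.integer), lapply(ts$counts, as.integer))
  expect_equal(ts2$final_sample_count, ts$final_sample_count)
  expect_equal(ts2$selection$gamma, -20)
  expect_equal(ts2$demography$sizes, c(300))
})
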