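test_that("without mutation there are no segregating sites", {
  dem <- constant_model(300)
  samp <- sample_config(S = 600, f = 0.02, tolerance = 0, n = 6)
  ts <- sample_trajectories_at_frequency(dem, 0, samp, 1, seed = 2)
  loc0 <- locus_params(u = 0, r = 1e-8, l = 1e5, focal_pos = 0)
  hs <- simulate_haplotypes(ts$counts[[1]], dem, loc0, n = 3, seed = 3)
  expect_equal(ncol(hs$genotypes), 0)
  pmf <- window_probabilities(ts$counts[[1]], dem, loc0, n = 3,
                              window_scheme(), reps = 5, seed = 4)
  expect_equal(pmf, c(0, 0, 0, 0, 0, 1))
})

test_that("haplotype sampling validates its preconditions", {
  dem <- constant_model(300)
  loc <- locus_params(u = 1e-7, r = 1e-7, l = 1e5, focal_pos = 0)
  expect_error(simulate_haplotypes(c(2L, 5L), dem, loc, n = 2), "copy number 1")
  expect_error(simulate_haplotypes(c(1L, 5L), dem, loc, n = 6), "exceeds")
  expect_error(simulate_haplotypes(c(1L, rep(700L, 3L)), dem, loc, n = 2),
               "inconsistent")
})

test_that("with r = 0 the pair no-difference probability follows T2", {
  dem <- constant_model(1000)
  samp <- sample_config(S = 2000, f = 0.01, tolerance = 0, n = 4)
  ts <- sample_trajectories_at_frequency(dem, -50, samp, 10, seed = 21)
  cc <- ts$counts[[which.max(allele_age(ts))]]
  u <- 2e-7
  loc <- locus_params(u = u, r = 0, l = 2.5e5, focal_pos = 0)
  sch <- window_scheme()
  reps <- 4000
  cnt <- haplodfe:::.window_counts_batch(list(cc), dem, loc, 2, sch, reps)
  emp_surv <- 1 - cumsum(as.numeric(cnt[1, ])) / reps  # P(L > boundary_j)
  t2 <- t2_distribution(cc)
  c0 <- cc[length(cc)]
  ana_surv <- vapply(sch$boundaries, function(d) {
    # the pair picks present-day copies with replacement: identical copies
    # (probability 1/c0) never differ; otherwise T2 governs the mutations
    1 / c0 + (1 - 1 / c0) * sum(t2$pmf * exp(-2 * u * t2$t * d))
  }, numeric(1))
  se <- sqrt(ana_surv * (1 - ana_surv) / reps)
  expect_true(all(abs(emp_surv[1:5] - ana_surv) < 3.5 * se + 0.01))
})

test_that("a long-fixed trajectory reduces to the neutral coalescent", {
  # derived copies at 2N - 1 for ~8N generations: a pair's T2 is essentially
  # the neutral pairwise coalescent time, so E[diffs] ~ 2 u l E[T2]
  N <- 200
  dem <- constant_model(N)
  cc <- c(1L, rep(2L * N - 1L, 8L * N))
  u <- 5e-7
  loc <- locus_params(u = u, r = 0, l = 5e4, focal_pos = 0)
  set.seed(31)
  diffs <- replicate(400, {
    hs <- simulate_haplotypes(cc, dem, loc, n = 2)
    sum(hs$genotypes[1, ] != hs$genotypes[2, ])
  })
  expected <- 2 * u * loc$l * t2_distribution(cc)$mean
  expect_lt(abs(mean(diffs) - expected),
            3.5 * sd(diffs) / sqrt(length(diffs)) + 0.05 * expected)
})

test_that("window probabilities are exchangeable and sum to one", {
  dem <- constant_model(500)
  samp <- sample_config(S = 1000, f = 0.01, tolerance = 0, n = 5)
  ts <- sample_trajectories_at_frequency(dem, 0, samp, 1, seed = 41)
  loc <- locus_params(u = 1.2e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  pmf <- window_probabilities(ts$counts[[1]], dem, loc, n = 5, sch,
                              reps = 40, seed = 42)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # relabeling haplotypes leaves the binned IBS records unchanged
  hs <- simulate_haplotypes(ts$counts[[1]], dem, loc, n = 5, seed = 43)
  d1 <- collect_ibs(list(hs), sch)
  hs_perm <- hs
  prm <- c(3, 1, 5, 2, 4)
  hs_perm$genotypes <- hs$genotypes[prm, ]
  d2 <- collect_ibs(list(hs_perm), sch)
  expect_equal(ibs_window_counts(d1, sch), ibs_window_counts(d2, sch))
})

test_that("stronger selection lengthens IBS tracts at a fixed frequency", {
  cfg <- hd_const_scaled()
  sch <- window_scheme()
  mean_idx <- vapply(c(0, 50, 100), function(g) {
    ts <- sample_trajectories_at_frequency(cfg$demography, g, cfg$sample,
                                           400, seed = 60 + g)
    cnt <- haplodfe:::.window_counts_batch(ts$counts, cfg$demography,
                                           cfg$locus, 2, sch, reps = 30)
    tot <- colSums(cnt)
    sum(seq_len(6) * tot) / sum(tot)
  }, numeric(1))
  expect_lt(mean_idx[1], mean_idx[2])
  expect_lt(mean_idx[2], mean_idx[3])
})

test_that("focal-left and focal-midpoint conventions agree per direction", {
  cfg <- hd_const_scaled()
  sch <- window_scheme()
  ts <- sample_trajectories_at_frequency(cfg$demography, 0, cfg$sample,
                                         300, seed = 71)
  left <- haplodfe:::.window_counts_batch(ts$counts, cfg$demography,
                                          cfg$locus, 2, sch, reps = 30,
                                          directions = 1L)
  mid <- haplodfe:::.window_counts_batch(ts$counts, cfg$demography,
                                         cfg$locus, 2, sch, reps = 15,
                                         directions = 2L)
  p1 <- colSums(left) / sum(left)
  p2 <- colSums(mid) / sum(mid)
  n1 <- sum(left)
  n2 <- sum(mid)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  expect_true(all(abs(p1 - p2) < 4 * se + 0.01))
})
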