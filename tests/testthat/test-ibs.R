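test_that("pairwise IBS lengths scan to the first discordant site", {
  pos <- c(30e3, 60e3, 240e3)
  a <- c(0, 1, 0)
  b <- c(0, 0, 1)
  expect_equal(pairwise_ibs_length(a, b, pos, 0, "down"), 60e3)
  expect_equal(pairwise_ibs_length(a, a, pos, 0, "down"), Inf)
  expect_equal(pairwise_ibs_length(c(1, 0, 0), c(0, 0, 0), pos, 0, "down"),
               30e3)
  # upstream direction measures toward smaller coordinates
  expect_equal(pairwise_ibs_length(a, b, pos, 3e5, "up"), 3e5 - 240e3)
  # missing genotypes are skipped as non-informative
  expect_equal(pairwise_ibs_length(c(NA, 1, 0), c(1, 0, 1), pos, 0, "down"),
               60e3)
})

test_that("window binning is half-open with an open-ended final window", {
  sch <- window_scheme()
  expect_equal(sch$M, 6L)
  expect_equal(bin_length(c(1, 50000, 50001, 250000, 250001, Inf), sch),
               c(1L, 1L, 2L, 5L, 6L, 6L))
  sch4 <- window_scheme(c(1e4, 2e4, 3e4))
  expect_equal(sch4$M, 4L)
  expect_error(window_scheme(c(2e4, 1e4)))
})

test_that("the record-count identity holds exactly", {
  expect_equal(ibs_record_count(300, 40, 2), 468000)
  expect_equal(ibs_record_count(30000, 40, 2), 46800000)
  expect_equal(ibs_record_count(1, 2, 1), 1)
  # per-locus n vector form
  expect_equal(ibs_record_count(c(4, 6), directions = 2),
               2 * (choose(4, 2) + choose(6, 2)))
})

test_that("collect_ibs keeps the bookkeeping and ordering invariants", {
  dem <- constant_model(300)
  samp <- sample_config(S = 600, f = 0.02, tolerance = 0, n = 6)
  loc <- locus_params(u = 2e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  set.seed(5)
  ts <- sample_trajectories_at_frequency(dem, 0, samp, 3)
  loci <- lapply(ts$counts, function(cc)
    simulate_haplotypes(cc, dem, loc, n = 5))
  d <- collect_ibs(loci, sch)
  expect_s3_class(d, "ibs_data")
  expect_equal(nrow(d), 2 * 3 * choose(5, 2))
  expect_true(all(d$window == bin_length(d$length_bp, sch)))
  # locus order does not change the pooled windows
  d_rev <- collect_ibs(rev(loci), sch)
  expect_equal(ibs_window_counts(d, sch), ibs_window_counts(d_rev, sch))
  # a locus with fewer than 2 derived haplotypes is skipped with a warning
  one <- loci[[1]]
  one$derived <- c(TRUE, rep(FALSE, 4))
  expect_warning(collect_ibs(c(loci, list(one)), sch), "fewer than 2")
})

test_that("masking singletons never shortens an IBS tract", {
  dem <- constant_model(300)
  samp <- sample_config(S = 600, f = 0.02, tolerance = 0, n = 6)
  loc <- locus_params(u = 3e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  set.seed(6)
  ts <- sample_trajectories_at_frequency(dem, 0, samp, 4)
  loci <- lapply(ts$counts, function(cc)
    simulate_haplotypes(cc, dem, loc, n = 5))
  d_raw <- collect_ibs(loci, sch)
  d_mask <- collect_ibs(loci, sch, mask_singletons = TRUE)
  key <- paste(d_raw$locus_id, d_raw$direction, d_raw$pair)
  keym <- paste(d_mask$locus_id, d_mask$direction, d_mask$pair)
  expect_equal(key, keym)
  expect_true(all(d_mask$length_bp >= d_raw$length_bp))
  expect_true(all(d_mask$window >= d_raw$window))
})
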