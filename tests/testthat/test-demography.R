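test_that("demographic models validate their epoch structure", {
  expect_error(demographic_model(c(1, 100)), "sizes")
  expect_error(demographic_model(c(100, 100), c(Inf, 0.2)), "durations")
  expect_error(demographic_model(c(100, 100, 100), c(Inf, Inf, 5)),
               "most ancient")
  m <- expansion_model(5000, 50000, 100)
  expect_equal(ancient_size(m), 5000)
  expect_equal(pop_size_at(m, c(0, 50, 99, 100, 1e6)),
               c(50000, 50000, 50000, 5000, 5000))
})

test_that("population-scaled locus rates match the study parameterization", {
  dem <- constant_model(10000)
  loc <- locus_params(u = 1.2e-8, r = 1.0e-8, l = 5e5)
  expect_equal(locus_theta(dem, loc), 240)
  expect_equal(locus_rho(dem, loc), 200)
})

test_that("rescaling keeps 4Ns, theta and rho invariant", {
  dem <- constant_model(10000)
  sel <- selection_params(-100)
  loc <- locus_params(u = 1.2e-8, r = 1.0e-8, l = 5e5)
  rs <- rescale_model(dem, sel, loc, 5)
  expect_equal(ancient_size(rs$demography), 2000)
  # s = gamma / 4N doubles its per-generation value via u,r,s scaling
  expect_equal(rs$selection$gamma, -100)
  expect_equal(locus_theta(rs$demography, rs$locus), locus_theta(dem, loc))
  expect_equal(locus_rho(rs$demography, rs$locus), locus_rho(dem, loc))
  # factor 1 is the identity
  rs1 <- rescale_model(dem, sel, loc, 1)
  expect_equal(rs1$demography$sizes, dem$sizes)
  expect_equal(rs1$locus$u, loc$u)
  # expansion model: sizes scale, epoch times do not
  ex <- expansion_model(5000, 50000, 100)
  rs5 <- rescale_model(ex, sel, loc, 5)
  expect_equal(rs5$demography$sizes, c(1000, 10000))
  expect_equal(rs5$demography$durations[2], 100)
  expect_equal(locus_theta(rs5$demography, rs5$locus), locus_theta(ex, loc))
  expect_error(rescale_model(constant_model(5), sel, loc, 5), "size < 2")
})

test_that("sample frequency bands match the cohort setups", {
  s1 <- sample_config(S = 4000, f = 0.01, tolerance = 0, n = 40)
  expect_equal(haplodfe:::.band_counts(s1$S, s1$f, s1$tolerance), c(40L, 40L))
  s2 <- sample_config(S = 7242, f = 0.01, tolerance = 0.0005, n = 72)
  expect_equal(haplodfe:::.band_counts(s2$S, s2$f, s2$tolerance), c(69L, 76L))
  expect_error(sample_config(S = 100, f = 0.01), "round")
  expect_error(sample_config(S = 4000, f = 0.01, tolerance = 0, n = 41), "band")
})
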