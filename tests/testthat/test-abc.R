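test_that("ABC configurations validate their priors", {
  expect_error(abc_config("constant", list(), 100), "priors")
  expect_error(abc_config("constant", list(N = c(100, 50)), 100), "improper")
  expect_error(abc_config("expansion", list(n_ancient = c(1, 2)), 100),
               "priors")
  expect_error(abc_config("constant", list(N = c(100, 200)), 100,
                          acceptance_quantile = 0.7))
  cfg <- abc_config("expansion",
                    list(n_ancient = c(100, 1000), n_recent = c(1000, 1e4),
                         t_expansion = c(10, 200)), 100)
  expect_s3_class(cfg, "abc_config")
})

test_that("neutral summaries are window proportions", {
  dem <- constant_model(400)
  samp <- sample_config(S = 800, f = 0.02, tolerance = 0, n = 6)
  loc <- locus_params(u = 1.5e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  s <- neutral_summaries(dem, samp, loc, sch, A = 20, reps = 5, seed = 1)
  expect_length(s, 6)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  s0 <- neutral_summaries(dem, samp, locus_params(u = 0, r = 1e-7, l = 5e5),
                          sch, A = 5, reps = 3, seed = 2)
  expect_equal(s0, c(0, 0, 0, 0, 0, 1))
})

test_that("population size separates the neutral summaries", {
  samp <- sample_config(S = 2000, f = 0.01, tolerance = 0, n = 6)
  loc <- locus_params(u = 1.2e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  set.seed(3)
  A <- 120
  reps <- 10
  s_small <- neutral_summaries(constant_model(400), samp, loc, sch, A, reps)
  s_big <- neutral_summaries(constant_model(3000), samp, loc, sch, A, reps)
  npair <- A * reps * 2
  se <- sqrt(s_small * (1 - s_small) / npair + s_big * (1 - s_big) / npair)
  expect_true(any(abs(s_small - s_big) > 3 * se))
})

test_that("rejection ABC accepts the closest quantile", {
  dem <- constant_model(400)
  samp <- sample_config(S = 800, f = 0.02, tolerance = 0, n = 6)
  loc <- locus_params(u = 1.5e-7, r = 1e-7, l = 5e5)
  sch <- window_scheme()
  cfg <- abc_config("constant", list(N = c(150, 1500)), n_draws = 40,
                    acceptance_quantile = 0.1, A = 10, reps = 4)
  obs <- neutral_summaries(dem, samp, loc, sch, A = 10, reps = 4, seed = 4)
  post <- abc_reject(obs, cfg, samp, loc, sch, seed = 5)
  expect_equal(nrow(post$accepted), ceiling(0.1 * 40))
  expect_lte(max(post$accepted$distance),
             min(post$draws$distance[!post$draws$accepted]))
  expect_named(post$point_estimates, "N")
  # degenerate summaries (u = 0 everywhere) are rejected as uninformative
  expect_error(abc_reject(c(0, 0, 0, 0, 0, 1), cfg, samp,
                          locus_params(u = 0, r = 1e-7, l = 5e5), sch,
                          seed = 6),
               "degenerate")
})
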