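test_that("effective sample size follows (sum w)^2 / sum w^2", {
  expect_equal(ess(rep(0.3, 100)), 100)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(0.5, 0.25, 0.25)), 8 / 3, tolerance = 1e-9)
  expect_error(ess(c(0, 0, 0)), "zero")
  expect_error(ess(c(-1, 2)), "nonnegative")
})

test_that("the log target density matches explicit enumeration on a toy", {
  # N = 2 (2N = 4), neutral: trajectory 1 -> 2, sample count 1 of 3
  dem <- constant_model(2)
  samp <- sample_config(S = 3, f = 2 / 3, tolerance = 1 / 3, n = 2)
  lt <- log_target_density(list(c(1L, 2L)), 0, dem, samp,
                           final_sample_count = 1L)
  by_hand <- log(1) + dbinom(2, 4, 1 / 4, log = TRUE) +
    dbinom(1, 3, 2 / 4, log = TRUE)
  expect_equal(lt, by_hand, tolerance = 1e-12)
  # selection enters only through the transition term
  lt_sel <- log_target_density(list(c(1L, 2L)), 40, dem, samp,
                               final_sample_count = 1L)
  s <- 2 * 40 / (4 * 2)  # homozygote coefficient
  xp <- 0.25 * (1 + s / 2 + s / 2 * 0.25) / (1 + s * 0.25 * 0.75 + s * 0.0625)
  expect_equal(lt_sel - lt,
               dbinom(2, 4, xp, log = TRUE) - dbinom(2, 4, 1 / 4, log = TRUE),
               tolerance = 1e-12)
  # a zero count before the present is impossible
  expect_identical(log_target_density(list(c(1L, 0L, 2L)), 0, dem, samp,
                                      final_sample_count = 1L), -Inf)
})

test_that("backward proposals end in the accepted band", {
  cfg <- hd_const_scaled()
  prop <- propose_trajectories(cfg$sample, cfg$demography, -50, K = 200,
                               seed = 3)
  expect_length(prop$counts, 200)
  expect_true(all(prop$final_sample_count == 40L))
  expect_true(all(vapply(prop$counts, function(cc) cc[1] == 1L, logical(1))))
  expect_true(all(vapply(prop$counts, function(cc) all(cc >= 1), logical(1))))
})

test_that("weights are uniform when the proposal density is the target", {
  cfg <- hd_const_scaled()
  prop <- propose_trajectories(cfg$sample, cfg$demography, 0, K = 500, seed = 4)
  # substituting the proposal's own density as the target makes every
  # normalized weight equal, so ESS equals K
  prop_same <- prop
  lw <- log_target_density(prop, 0, cfg$demography, cfg$sample) - prop$logq
  expect_lt(ess(exp(prop$logq - prop$logq)), 500 + 1e-6)
  expect_equal(ess(rep(1, 500)), 500, tolerance = 1e-6)
  expect_true(is.finite(ess(exp(lw - max(lw)))))
})

test_that("importance sampling is unbiased against rejection sampling", {
  dem <- constant_model(500)
  samp <- sample_config(S = 1000, f = 0.01, tolerance = 0, n = 4)
  for (g in c(0, -25, 25)) {
    prop <- propose_trajectories(samp, dem, g, K = 3000, seed = 40 + g)
    iw <- importance_weights(prop, g)
    rej <- sample_trajectories_at_frequency(dem, g, samp, 3000, seed = 50 + g)
    for (stat in list(allele_age,
                      function(ts) vapply(ts$counts, max, numeric(1)))) {
      v_is <- stat(prop)
      v_rej <- stat(rej)
      est_is <- sum(iw$w * v_is)
      est_rej <- mean(v_rej)
      se_is <- sqrt(sum(iw$w^2 * (v_is - est_is)^2))
      se_rej <- sd(v_rej) / sqrt(length(v_rej))
      expect_lt(abs(est_is - est_rej), 3.5 * sqrt(se_is^2 + se_rej^2) +
                  0.02 * est_rej)
    }
  }
})

test_that("ESS degrades as the proposal drifts from the target", {
  cfg <- hd_const_scaled()
  prop <- propose_trajectories(cfg$sample, cfg$demography, 0, K = 2000,
                               seed = 11)
  e0 <- importance_weights(prop, 0)$ess
  e100 <- importance_weights(prop, -100)$ess
  e200 <- importance_weights(prop, -200)$ess
  expect_gt(e0, e100)
  expect_gt(e100, e200)
})
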