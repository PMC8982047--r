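# shared small-model configurations used across test files

hd_const <- function(N = 1000) constant_model(N)

# rescaled constant-size study model: N = 10,000 with theta = 4Nul = 240 and
# rho = 200, brought down by a factor of 10 (rates up, sizes down)
hd_const_scaled <- function() {
  list(demography = constant_model(1000),
       locus = locus_params(u = 1.2e-7, r = 1.0e-7, l = 5e5),
       sample = sample_config(S = 4000, f = 0.01, tolerance = 0, n = 20))
}

# the expansion study model (5,000 -> 50,000 at 100 generations) under the
# same factor-10 rescaling; epoch times are unchanged by rescale_model
hd_expansion_scaled <- function() {
  rs <- rescale_model(expansion_model(5000, 50000, 100), selection_params(0),
                      locus_params(u = 1.2e-8, r = 1.0e-8, l = 5e5), 10)
  rs$sample <- sample_config(S = 4000, f = 0.01, tolerance = 0, n = 20)
  rs
}

# direct (independent) Wright-Fisher step used as an oracle in tests:
# fitnesses 1, 1+s, 1+2s with s = gamma / 4N
hd_wf_step <- function(j, twoN, gamma, N) {
  s <- gamma / (4 * N)
  x <- j / twoN
  xp <- x * (1 + s + s * x) / (1 + 2 * s * x)
  rbinom(length(j), twoN, xp)
}

# memoised heavy objects shared across acceptance blocks
hd_cache <- new.env(parent = emptyenv())
hd_memo <- function(key, expr) {
  if (!exists(key, envir = hd_cache)) assign(key, force(expr), envir = hd_cache)
  get(key, envir = hd_cache)
}
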