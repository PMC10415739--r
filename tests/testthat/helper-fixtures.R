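# Shared fixtures for the test suite. Everything is generated in code at
# test time; the cache avoids recomputing the pool equilibrium across
# test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

paper_rate_clean <- function() rate_parameters(3.2e4, "clean")
paper_rate_pool <- function() rate_parameters(2.7e4, "pool")

# small N25 pool equilibrated against the synthetic example invader
small_pool_eq <- function(n = 3000, seed = 42) {
  key <- sprintf("pool_eq_%d_%d", n, seed)
  if (is.null(.fixture_cache[[key]])) {
    pool <- generate_random_pool(n, 25, seed = seed)
    .fixture_cache[[key]] <- pool_equilibrium(example_invader(), pool,
                                              invader_conc = 500e-9,
                                              pool_conc = 5e-6)
  }
  .fixture_cache[[key]]
}

# an emulsion at the standard composition (fixed xi = 0.5 with production
# jitter), optionally carrying the random pool
std_emulsion <- function(n_droplets, seed, pool = FALSE, xi_sd = 0.01,
                         radius_cv = 0.03, calibration = NULL) {
  eq <- if (pool) small_pool_eq() else NULL
  cfg <- emulsion_config(
    n_droplets = n_droplets, radius_mean = 15, radius_cv = radius_cv,
    pool_stock = if (pool) 5e-6 else 0,
    pool_size = if (pool) nrow(eq$interactions) else 10000,
    xi_sd = xi_sd
  )
  generate_emulsion(cfg, pool_interactions = eq$interactions, seed = seed,
                    calibration = calibration)
}

# independent numeric oracle for the two-state equilibrium: root of the
# mass-balance equation K (a - C)(r - C) = C on [0, min(a, r)]
theta_root_oracle <- function(ddG, a, r, model = energy_model()) {
  k_eq <- exp(-ddG / model$kT)
  f <- function(cc) k_eq * (a - cc) * (r - cc) - cc
  fp <- function(cc) k_eq * (2 * cc - a - r) - 1
  cc <- stats::uniroot(f, c(0, min(a, r)), tol = 1e-18)$root
  # polish to machine precision (uniroot stalls on roots << interval)
  for (i in 1:60) {
    step <- f(cc) / fp(cc)
    cc_new <- min(min(a, r), max(0, cc - step))
    if (cc_new == cc) break
    cc <- cc_new
  }
  cc / a
}
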