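# shared fixtures built in code

default_params <- minimal_params()
default_th <- thresholds(default_params)

sample_fixture <- function(name, U_G, beta = 0, n = 2000, seed = 1,
                           objective = NULL, params = default_params) {
  fx <- fixture(name, U_G = U_G, params = params)
  poly <- flux_polytope(fx$net, crowding = fx$crowding)
  ell <- round_polytope(poly, seed = seed)
  cfg <- sampler_config(n, beta = beta, objective = objective, seed = seed + 1)
  list(fx = fx, poly = poly, ell = ell,
       ss = hit_and_run(poly, cfg, rounding = ell))
}

# a small random closed network: k metabolites, m reactions with random
# sparse integer stoichiometry plus exchange reactions so nothing is orphan
random_network <- function(k, m, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(0, k, m)
    for (j in seq_len(m)) {
      picks <- sample(k, sample(2:min(3, k), 1))
      S[picks, j] <- sample(c(-2L, -1L, 1L, 2L), length(picks), replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  dimnames(S) <- list(paste0("m", seq_len(k)), paste0("r", seq_len(m)))
  metabolic_network(S, lb = rep(-10, m), ub = rep(10, m))
}

expect_close <- function(actual, expected, tol = 1e-8, scale = 1) {
  expect_lt(max(abs(actual - expected) / (scale + abs(expected))), tol)
}

# mixed absolute/relative deviation used for the analytic-vs-LP contract
mixed_dev <- function(a, b) max(abs(a - b) / (1 + abs(b)))
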