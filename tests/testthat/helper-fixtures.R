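# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# reduced MCMC settings for tests: 2 chains x 1000 retained each
light_mcmc <- function(seed = 1L, iterations = 1500L, burn_in = 500L,
                       n_chains = 2L, thinning = 1L) {
  mcmc_config(n_chains = n_chains, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed)
}

# 30 physicians, continuous ratings: enough physicians that any exploratory
# selection (up to 9 skills x 3 parameter types = 27 predictors) stays
# feasible in the downstream competence regressions
fix_model <- function() cached("model", {
  sample_true_model(n_physicians = 30, heterogeneity = 0.08, seed = 11)
})

fix_ratings <- function() cached("ratings", {
  simulate_ratings(fix_model(), consultations = 15, discretize = FALSE, seed = 12)
})

fix_fits <- function() cached("fits", {
  fit_all_nodes(fix_ratings(), mcmc = light_mcmc(13))
})

fix_networks <- function() cached("networks", {
  fits <- fix_fits()
  nets <- lapply(fits$physician_ids, function(id) {
    build_physician_network(fits, fix_ratings(), id)
  })
  names(nets) <- fits$physician_ids
  nets
})

fix_population <- function() cached("population", {
  build_population_network(fix_fits(), fix_ratings())
})

fix_scores <- function() cached("scores", {
  obs <- simulate_observer_scores(fix_model(), seed = 14)
  aggregate_observer(obs)
})

fix_table <- function() cached("table", {
  assemble_predictors(fix_networks(), skills = c(1, 6, 7), scores = fix_scores())
})

# dense per-physician data (200 consultations) with marked heterogeneity:
# used where physician-specific edge weights must be estimated precisely
fix_dense_networks <- function() cached("dense_networks", {
  m <- sample_true_model(n_physicians = 6, heterogeneity = 0.15, seed = 31)
  r <- simulate_ratings(m, consultations = 200, discretize = FALSE, seed = 32)
  fits <- fit_all_nodes(r, mcmc = light_mcmc(33))
  nets <- lapply(fits$physician_ids, function(id) {
    build_physician_network(fits, r, id)
  })
  names(nets) <- fits$physician_ids
  list(model = m, networks = nets)
})

# single-physician continuous data (n = 500) with known precision matrix:
# the multilevel model collapses to an ordinary Bayesian regression, so the
# coefficients have an OLS oracle and an analytic truth
fix_single <- function() cached("single", {
  m <- sample_true_model(n_physicians = 1, heterogeneity = 0,
                         mean_heterogeneity = 0, seed = 21)
  r <- simulate_ratings(m, consultations = 500, discretize = FALSE, seed = 22)
  list(model = m, ratings = r)
})

fix_single_fit <- function(outcome = 4L) {
  cached(paste0("single_fit_", outcome), {
    s <- fix_single()
    fit_nodewise(s$ratings, outcome = outcome, mcmc = light_mcmc(23 + outcome))
  })
}

# analytic truth: directed edge k -> j implied by a precision matrix
true_edge_matrix <- function(Omega) {
  K <- nrow(Omega)
  W <- matrix(0, K, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    if (j != k) W[k, j] <- -Omega[j, k] / Omega[j, j]
  }
  W
}
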