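# Shared fixtures. The recovery workflow (simulate -> hyperparameter
# search -> final fit -> shuffled-prior control) is expensive, so it is
# computed once per session and memoized; several test files read it.

.fixture_cache <- new.env(parent = emptyenv())

# Small dataset for cheap end-to-end checks.
small_sim <- function(seed = 7) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_grn_data(simulation_config(
      n_cells = 120, n_genes = 60, n_tfs = 4, edge_density = 0.12,
      seed = seed))
  .fixture_cache[[key]]
}

fast_config <- function(...) {
  pmfgrn_config(max_steps = 400, eval_interval = 50, patience = 4,
                summary_mc_samples = 500, ...)
}

# The full-size recovery study: 500 cells x 200 genes x 8 TFs at 5%
# density, prior corrupted at fn 0.2 / fp 0.005; 4-configuration search
# scored by validation AUPRC, final fit on the full prior with
# importance-weighted stopping, and a shuffled-prior control fit.
recovery_fixture <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  sim <- simulate_grn_data(simulation_config(seed = 101))
  grid <- pmfgrn_default_grid(sigma_a = c(0.5, 1), sigma_u = 1,
                              beta = c(1, 4),
                              base = pmfgrn_config(seed = 101))
  search <- pmfgrn_search(sim$W, sim$prior, grid, fraction = 0.2,
                          seed = 101)
  final <- final_fit(sim$W, sim$prior, search$best_config)
  shuffled_prior <- shuffle_prior(sim$prior, seed = 202)
  shuffled_fit <- pmf_grn(sim$W, shuffled_prior, search$best_config,
                          stopping = "iw_log_marginal")
  shuffled <- summary(shuffled_fit)
  .fixture_cache$recovery <- list(
    sim = sim, grid = grid, search = search, final = final,
    fit = attr(final, "fit"), shuffled = shuffled)
  .fixture_cache$recovery
}
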