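# Small in-code fixtures shared across test files.

# Minimal complete panel: n areas x T months x 4 strata, constant or
# supplied cases.
tiny_panel <- function(n_areas = 2, T = 2, cases = 1L, population = 100) {
  areas <- sprintf("a%02d", seq_len(n_areas))
  grid <- expand.grid(area_id = areas, month = seq_len(T),
                      age_group = c("under15", "over15"),
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$year <- 2010L
  grid$cases <- as.integer(rep_len(cases, nrow(grid)))
  grid$population <- rep_len(population, nrow(grid))
  surveillance_panel(grid)
}

# Desk-scale simulated dataset used by several modules.
desk_sim <- function(seed = 42, omega = 0.2, T = 24, nrow_lat = 6,
                     ncol_lat = 6, ...) {
  g <- make_lattice_adjacency(nrow_lat, ncol_lat)
  tr <- ground_truth(g, seed = seed, omega = omega, ...)
  sim <- simulate_dataset(g, T, tr, seed = seed)
  c(sim, list(graph = g))
}

# intercept-only design
ones <- function(n) matrix(1, n, 1)

fast_config <- function(seed = 1, total = 2000, burn = 500, thin = 5) {
  run_config(mcmc = list(seed = seed, total_iterations = total,
                         burn_in = burn, thin = thin))
}
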