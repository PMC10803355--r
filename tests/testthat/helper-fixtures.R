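# Shared fixtures: short simulation horizons for unit-level runs, trajectory
# builders with exact distances, and a memoised scaled-grid batch reused by
# the grid-level acceptance checks.

quick_params <- function(duration = 600, warmup = 120, sigma = 0.5, ...) {
  sim_params(duration = duration, warmup = warmup,
             driver_imperfection = sigma, ...)
}

# trajectory table from per-vehicle speed sequences (km/h), dt = 1 s
make_traj <- function(...) {
  speeds <- list(...)
  do.call(rbind, lapply(seq_along(speeds), function(i) {
    v <- speeds[[i]]
    data.frame(vehicle_id = i, time_s = seq_along(v),
               position_m = cumsum(v / 3.6), speed_kmh = v, lane = 0L)
  }))
}

# one world row for sim_step tests
world_row <- function(vehicle_id, driver_id, position_m, speed_ms, lane = 0L) {
  data.frame(vehicle_id = vehicle_id, driver_id = driver_id,
             position_m = position_m, speed_ms = speed_ms, lane = lane)
}

# a single-driver "population" table with the given attributes
one_driver <- function(group = "B", dffs_kmh = 108, telematics = FALSE, n = 1) {
  data.frame(driver_id = seq_len(n), group = group, dffs_kmh = dffs_kmh,
             telematics = telematics, stringsAsFactors = FALSE)
}

# The scaled factorial grid used by the grid-level acceptance checks:
# all four layouts x telematics {0,5,10} x B {10,30,50} x C {1,3,5}
# x demand {500,2000,3500}, five common seeds. Computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())

scaled_grid_results <- function() {
  if (is.null(.acceptance_cache$grid)) {
    grid <- list(sec_type = c("FIX1", "FIX2", "FIX3", "P2P"),
                 telematics_pct = c(0, 5, 10),
                 pct_B = c(10, 30, 50),
                 pct_C = c(1, 3, 5),
                 demand_vph = c(500, 2000, 3500))
    specs <- expand_seeds(enumerate_scenarios(grid), n_seeds = 5,
                          master_seed = 20240122)
    .acceptance_cache$grid <- run_batch(specs)
  }
  .acceptance_cache$grid
}
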