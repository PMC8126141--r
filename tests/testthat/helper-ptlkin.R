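# Shared fixtures. All fixtures are computed, never stored.

default_constants <- model_constants()

selective <- treatment_scenario("selective_nonsynergistic")
selective_no2 <- treatment_scenario("selective_synergistic")
nonselective <- treatment_scenario("nonselective_nonsynergistic")

# A short uniform grid for fast end-to-end runs in unit tests (~1.2e3
# points over the full 100 s horizon; coarse but cheap).
coarse_grid <- function() time_grid(dt1 = 1e-4, dt2 = 1e-2, dt3 = 1e-1)

# Random physically-plausible states for property-style tests.
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    y <- stats::runif(16, min = 0, max = 1e-3)
    names(y) <- state_names()
    y
  })
}

# Memoized medium-resolution reference run reused across test files.
.runs <- new.env(parent = emptyenv())
cached_run <- function(kd1 = 920, cat0 = 1e-8, scenario = selective) {
  key <- sprintf("%g|%g|%s", kd1, cat0, scenario$regime)
  if (is.null(.runs[[key]]))
    .runs[[key]] <- simulate_cell(cell_phenotype(kd1, cat0), scenario,
                                  grid = sweep_time_grid())
  .runs[[key]]
}

# Normalized per-species discrepancy between two trajectories sampled at
# the same times: max_t |a - b| scaled by each species' own magnitude.
traj_discrepancy <- function(a, b) {
  vapply(state_names(), function(v) {
    s <- max(abs(b[[v]]))
    if (s > 0) max(abs(a[[v]] - b[[v]])) / s else max(abs(a[[v]]))
  }, numeric(1))
}
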