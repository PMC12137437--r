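# Shared fixtures for the test suite.  Expensive scenario runs are
# memoized so several tests can interrogate the same trajectory.

tp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, tp_cache)) assign(key, force(expr), tp_cache)
  get(key, tp_cache)
}

default_params <- function() cached("params", model_parameters())

default_homeo <- function() cached("homeo",
                                   solve_homeostasis(default_params()))

small_domain <- function(n = 60, R = 15)
  make_domain(list(mode = "radial_1d", R = R, n_cells = n))

# the scaled-down study grid used by scenario-level tests: 1D disk of
# radius 15 at quarter-unit resolution
test_scenario <- function(mode = "both", t_end = 60, seeds = list(seed_spec()),
                          therapy = therapy_parameters(), overrides = list(),
                          output_every = 5, n = 60) {
  scenario(macrophage_mode = mode, seeds = seeds,
           domain = list(mode = "radial_1d", R = 15, n_cells = n),
           t_end = t_end, therapy = therapy, output_every = output_every,
           param_overrides = overrides)
}

cached_run <- function(key, ...) cached(key, run_scenario(test_scenario(...)))

# plain-list view used for exact round-trip comparisons
params_as_list_public <- function(p) {
  out <- unclass(p)
  out$mu <- unname(out$mu)
  out$d_drag <- unname(out$d_drag)
  out
}

# uniform phase state helper
uniform_phases <- function(domain, h = 0, c = 0, v = 0, M1 = 0, M1p = 0,
                           M2 = 0, int = 0)
  phase_state(domain, h = h, c = c, v = v, M1 = M1, M1p = M1p, M2 = M2,
              int = int)
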