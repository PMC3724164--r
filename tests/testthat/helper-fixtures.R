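# Shared fixtures: default kinetics and small scenario builders.

default_params <- kinetic_params()

# a small centered-source scenario, cheap enough for property loops
small_source_scenario <- function(domain = c(40, 40), h = 1, r = 4,
                                  center = NULL, params = default_params) {
  build_single_source_scenario(h = h, domain_um = domain,
                               disc_radius_um = r, disc_center = center,
                               params = params)
}

# scenario with an initial MMP blob but no Dirichlet source anywhere
sourceless_scenario <- function(params = default_params) {
  grid <- grid_spec(1, 31, 25)
  itf <- interface_spec(shape_circle(c(8, 8), 3), role = "inert_cell",
                        bc_value = 0, label = "obstacle")
  M0 <- matrix(0, grid$nx, grid$ny)
  M0[12:18, 10:16] <- 0.8
  new_scenario(grid, list(itf), params, initial_M = M0, id = "sourceless")
}

run_steps <- function(scenario, n, config = solver_config()) {
  st <- build_stencil(scenario)
  dt <- stable_dt(scenario$params, scenario$grid, config)
  state <- initial_state(scenario)
  for (i in seq_len(n))
    state <- solver_step(state, scenario, st, dt, config)
  state
}
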