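test_that("stable explicit time step scales with h^2 and dimensionality", {
  p <- default_params
  g2 <- grid_spec(1, 10, 10)
  expect_equal(stable_dt(p, g2), 0.8 * 1 / (4 * 0.8))               # 0.25 s
  expect_equal(stable_dt(p, grid_spec(10, 10, 10)), 25)
  expect_equal(stable_dt(p, g2, solver_config(dt_safety = 1)), 0.3125)
  expect_equal(stable_dt(p, grid_spec(1, 10, 1)), 0.8 / (2 * 0.8))  # 1-D
  p0 <- kinetic_params(D0 = 0)
  expect_equal(stable_dt(p0, g2), solver_config()$snapshot_interval_s)
})

test_that("ghost extrapolation enforces the Dirichlet value at the interface", {
  # interface midway between nodes: ghost = Mb/theta + (1 - 1/theta)*Mc
  expect_equal(gf_ghost_value(0, 1, 0.5), 2)
  expect_equal(gf_ghost_value(0.4, 1, 1), 1)   # neighbor on the interface
  # linear interpolation at the interface point recovers Mb for any theta
  for (th in c(0.2, 0.5, 0.9)) {
    mc <- 0.37
    ghost <- gf_ghost_value(mc, 1, th)
    expect_equal(mc + th * (ghost - mc), 1)
  }
  expect_error(gf_ghost_value(0, 1, 0), "theta")
})

test_that("a uniform field is a fixed point of ghost-free diffusion", {
  sc <- sourceless_scenario()
  M0 <- matrix(0.6, sc$grid$nx, sc$grid$ny)
  E <- sc$initial_E
  M1 <- diffusion_step(M0, E, sc, dt = 0.2)
  expect_equal(M1, M0, tolerance = 1e-14)
})

test_that("time steps above the stability limit are rejected", {
  sc <- small_source_scenario()
  expect_error(diffusion_step(sc$initial_M, sc$initial_E, sc, dt = 0.5),
               "stability limit")
})

test_that("compiled and reference stencils agree to machine precision", {
  sc <- build_duct_scenario(h = 4, domain_um = c(148, 148),
                               bm_center = c(74, 74), bm_radius_um = 30,
                               stromal_angles_deg = c(40, 200))
  set.seed(11)
  M <- matrix(runif(sc$grid$nx * sc$grid$ny), sc$grid$nx, sc$grid$ny)
  M[sc$inside_secreting] <- 1
  E <- sc$initial_E
  cfg_c <- solver_config(engine = "cpp")
  cfg_r <- solver_config(engine = "reference")
  st <- build_stencil(sc)
  dt <- stable_dt(sc$params, sc$grid, cfg_c)
  Mc <- diffusion_step(M, E, sc, st, dt, cfg_c)
  Mr <- diffusion_step(M, E, sc, st, dt, cfg_r)
  expect_equal(Mc, Mr, tolerance = 1e-14)
})

test_that("reaction/decay uses exact exponential local updates", {
  p <- default_params
  M <- matrix(1); E <- matrix(0.85)
  up <- reaction_decay_step(M, E, p, dt = 1, freeze_E = TRUE)
  expect_equal(up$M[1, 1], exp(-(0.005 * 0.85 + 5e-5)))  # 0.995709
  expect_equal(up$E[1, 1], 0.85)
  # E reaches a tenth of its initial value at t = ln(10)/rE under M = 1
  up2 <- reaction_decay_step(M, E, p, dt = 460.517, freeze_E = FALSE)
  expect_equal(up2$E[1, 1], 0.085, tolerance = 1e-5)
  # no protease, no degradation
  up3 <- reaction_decay_step(matrix(0), E, p, dt = 100)
  expect_equal(up3$E[1, 1], 0.85)
})

test_that("E trajectory under constant M matches the closed form exactly", {
  p <- default_params
  E <- matrix(0.85, 3, 3)
  M <- matrix(0.7, 3, 3)
  dt <- 2.5
  for (k in 1:200) E <- reaction_decay_step(M, E, p, dt)$E
  expect_equal(max(abs(E - 0.85 * exp(-p$rE * 0.7 * 200 * dt))), 0,
               tolerance = 1e-10 * 0.85)
})

test_that("total MMP mass decays monotonically without sources", {
  sc <- sourceless_scenario()
  st <- build_stencil(sc)
  cfg <- solver_config()
  dt <- stable_dt(sc$params, sc$grid, cfg)
  state <- initial_state(sc)
  masses <- numeric(30)
  for (k in 1:30) {
    state <- solver_step(state, sc, st, dt, cfg)
    masses[k] <- sum(state$M)
  }
  expect_true(all(diff(masses) < 0))
  expect_true(all(state$M >= 0))
})

test_that("a centered source field keeps the full square symmetry", {
  sc <- small_source_scenario(domain = c(40, 40), r = 4)
  state <- run_steps(sc, 100)
  M <- state$M
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_lt(max(abs(M - M[nrow(M):1, ])), 1e-12)
  expect_lt(max(abs(M - M[, ncol(M):1])), 1e-12)
})

test_that("positivity and pointwise E decay hold on randomized scenarios", {
  set.seed(20240917)
  for (trial in 1:6) {
    r <- runif(1, 2, 6)
    cx <- runif(1, r + 2, 38 - r)
    cy <- runif(1, r + 2, 38 - r)
    sc <- small_source_scenario(domain = c(40, 40), r = r,
                                center = c(cx, cy))
    st <- build_stencil(sc)
    cfg <- solver_config()
    dt <- stable_dt(sc$params, sc$grid, cfg)
    state <- initial_state(sc)
    E_prev <- state$E
    for (k in 1:80) {
      state <- solver_step(state, sc, st, dt, cfg)
      expect_true(all(state$M >= 0))
      expect_true(all(state$E >= 0 & state$E <= 1))
      expect_true(all(state$E <= E_prev + 1e-15))
      E_prev <- state$E
    }
  }
})

test_that("1-D frozen-matrix steady state matches the analytic profile", {
  p <- default_params
  sc <- build_1d_column_scenario(length_um = 100, h = 1, params = p)
  run <- run_simulation(sc, solver_config(snapshot_interval_s = 1000,
                                          t_end_s = 4000))
  L <- length_scale(p$E_init, p)
  x <- sc$grid$x
  Mh <- run$snapshots[[length(run$snapshots)]]$M[, 1]
  sel <- x <= 5 * L
  expect_lt(max(abs(Mh[sel] - exp(-x[sel] / L))), 0.02)

  # refinement h -> h/2 reduces the error with observed order >= 1
  sc2 <- build_1d_column_scenario(length_um = 100, h = 0.5, params = p)
  run2 <- run_simulation(sc2, solver_config(snapshot_interval_s = 1000,
                                            t_end_s = 4000))
  M2 <- run2$snapshots[[length(run2$snapshots)]]$M[, 1]
  sel2 <- sc2$grid$x <= 5 * L
  err1 <- max(abs(Mh[sel] - exp(-x[sel] / L)))
  err2 <- max(abs(M2[sel2] - exp(-sc2$grid$x[sel2] / L)))
  expect_lt(err2, err1 / 2)
})

test_that("fully occluded frozen matrix admits no diffusion at all", {
  sc <- suppressWarnings(build_1d_column_scenario(length_um = 30, h = 1,
                                                  E_init = 1))
  state <- run_steps(sc, 50)
  expect_equal(state$M[1, 1], 1)          # the held boundary node
  expect_true(all(state$M[-1, 1] == 0))   # D = 0 blocks everything else
})

test_that("runs emit snapshots on schedule and t_end = 0 gives the initial state", {
  sc <- small_source_scenario()
  run0 <- run_simulation(sc, solver_config(t_end_s = 0))
  expect_equal(nrow(run0$summary), 1)
  expect_equal(run0$summary$t_s, 0)
  expect_identical(run0$snapshots[[1]]$M, sc$initial_M)

  run <- run_simulation(sc, solver_config(snapshot_interval_s = 30,
                                          t_end_s = 120))
  expect_equal(run$summary$t_s, c(0, 30, 60, 90, 120))
  expect_identical(snapshot_at(run, 1)$t, 60)
  expect_error(snapshot_at(run, 7), "no snapshot")
})
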