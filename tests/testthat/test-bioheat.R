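props <- material_properties()

test_that("a uniform field with no electrode and insulated boundaries is an equilibrium", {
  mesh <- build_mesh(vein_geometry(), nr = 19, nz = 40)
  cfg <- scenario_config(inlet_velocity = 0, duration = 1,
                         numerics = small_numerics())
  Tf <- temperature_field(309.15, mesh)
  emask <- matrix(FALSE, mesh$nr, mesh$nz)
  for (dt in c(1e-3, 0.1, 10)) {
    Tf2 <- step_temperature(Tf, NULL, mesh, emask, props, cfg, dt)
    expect_equal(max(abs(Tf2$T - 309.15)), 0, tolerance = 1e-9)
  }
})

test_that("with stagnant blood and all boundaries insulated the field relaxes to the electrode temperature", {
  geom <- vein_geometry(domain_length = 5e-3, electrode_length = 2e-3,
                        electrode_start_z = 1e-3)
  mesh <- build_mesh(geom, nr = 10, nz = 20)
  cfg <- scenario_config(inlet_velocity = 0, duration = 1, geometry = geom,
                         numerics = solver_settings(nr = 10, nz = 20))
  emask <- electrode_mask_at(mesh, electrode_state(1e-3, 0, 358))
  Tf <- temperature_field(309.15, mesh)
  for (s in 1:350) Tf <- step_temperature(Tf, NULL, mesh, emask, props, cfg, 2)
  expect_lt(max(abs(Tf$T - 358)), 0.5)
})

test_that("transient conduction into the wall matches the semi-infinite erf solution", {
  err <- rfavein:::erf_conduction_error(conduction_fixture(), props)
  expect_lt(err, 0.01)
  # blood-property variant on a blood-region slab
  fxb <- conduction_fixture(alpha = 0.492 / (1050 * 3820))
  expect_lt(rfavein:::erf_conduction_error(fxb, props, region = 1L), 0.01)
})

test_that("interface flux is continuous: uniform field and two-layer steady state", {
  mesh <- build_mesh(vein_geometry(), nr = 19, nz = 40)
  Tf <- temperature_field(320, mesh)
  chk <- interface_flux_check(Tf, mesh, props)
  expect_equal(max(abs(chk$mismatch)), 0, tolerance = 1e-12)
  expect_equal(max(abs(chk$q_lumen)), 0, tolerance = 1e-12)
  res <- rfavein:::two_layer_error(props)
  expect_lt(res$T_err, res$fixture$tolerance)
  expect_lt(res$flux_mismatch, 1e-8)
  # flux continuity forces the gradient ratio k_w / k_b across the face
  expect_equal(res$grad_ratio, props$k_w / props$k_b, tolerance = 1e-6)
})

test_that("a CFL-violating time step is rejected with the required dt in the message", {
  mesh <- build_mesh(vein_geometry(), nr = 19, nz = 40)
  cfg <- scenario_config(inlet_velocity = 40e-3, duration = 1,
                         numerics = small_numerics())
  fl <- plug_flow(mesh, 40e-3)
  Tf <- temperature_field(309.15, mesh)
  emask <- matrix(FALSE, mesh$nr, mesh$nz)
  expect_error(step_temperature(Tf, fl, mesh, emask, props, cfg, dt = 1),
               "CFL")
})

test_that("zero-duration runs return the initial condition only", {
  cfg <- scenario_config(inlet_velocity = 0, pullback_velocity = 0,
                         duration = 0, snapshot_times = numeric(0),
                         numerics = solver_settings(nr = 10, nz = 20))
  run <- run_transient(cfg)
  expect_length(run$snapshots, 1)
  expect_equal(run$snapshots[[1]]$time, 0)
  expect_equal(max(abs(run$snapshots[[1]]$T - 309.15)), 0)
})

test_that("heating grows monotonically and conservation diagnostics hold on a pullback run", {
  run <- cached_reduced_run(U = 0, V = 1e-3, duration = 3)
  # influenced volume is non-decreasing across snapshots
  fr <- vapply(run$snapshots, influenced_fraction, numeric(1),
               mesh = run$mesh, threshold_K = 310.15)
  expect_true(all(diff(fr) >= -1e-12))
  # energy bookkeeping and divergence stay at solver precision
  expect_lt(run$diagnostics$max_energy_residual, 1e-6)
  expect_lt(run$diagnostics$max_div_rel, 1e-8)
  # maximum principle: all snapshots inside [body, electrode] temperatures
  for (s in run$snapshots) {
    expect_gte(min(s$T), 309.15 - 1e-9)
    expect_lte(max(s$T), 358 + 1e-9)
  }
})

test_that("advected inflow pins the upstream lumen at body temperature", {
  run <- cached_reduced_run(U = 5e-3, V = 1e-3, duration = 2)
  Tf <- snapshot_at(run, 2)
  lum <- seq_len(run$mesh$i_lumen)
  expect_lt(max(abs(Tf$T[lum, 1] - 309.15)), 0.5)
})

test_that("a pullback that reaches the inlet truncates the run with a warning", {
  geom <- vein_geometry(domain_length = 20e-3, electrode_length = 5e-3,
                        electrode_start_z = 4e-3)
  cfg <- scenario_config(inlet_velocity = 0, pullback_velocity = 4e-3,
                         duration = 3, geometry = geom,
                         numerics = solver_settings(nr = 10, nz = 40))
  expect_warning(run <- run_transient(cfg), "truncated")
  expect_true(run$diagnostics$truncated)
  expect_lt(max(run$times), 1 + 1e-9)
})
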