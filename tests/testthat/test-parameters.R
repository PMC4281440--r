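test_that("default configuration passes validation and echoes the standard constants", {
  cfg <- validate_config(scenario_config())
  expect_equal(cfg$properties$rho_b, 1050)
  expect_equal(cfg$properties$mu_b, 0.0035)
  expect_equal(cfg$properties$rho_w, 1120)
  expect_equal(cfg$properties$c_pb, 3820)
  expect_equal(cfg$properties$c_pw, 3780)
  expect_equal(cfg$properties$k_b, 0.492)
  expect_equal(cfg$properties$k_w, 0.56)
  expect_equal(cfg$rheology$mu_inf, 0.0035)
  expect_equal(cfg$rheology$mu_0, 0.16)
  expect_equal(cfg$rheology$n, 0.2128)
  expect_equal(cfg$rheology$a, 0.64)
  expect_equal(cfg$rheology$lambda, 8.2)
  expect_equal(cfg$geometry$lumen_radius, 1.5e-3)
  expect_equal(cfg$geometry$wall_thickness, 0.4e-3)
  expect_equal(cfg$body_temperature, 309.15)
  expect_equal(cfg$electrode_temperature, 358)
})

test_that("invalid fields raise errors naming the field", {
  expect_error(material_properties(rho_b = -1), "rho_b")
  expect_error(material_properties(k_w = 0), "k_w")
  expect_error(carreau_yasuda(mu_0 = 0.001), "mu_0")
  expect_error(vein_geometry(electrode_radius = 2e-3), "electrode_radius")
  expect_error(scenario_config(electrode_temperature = 300), "electrode_temperature")
  expect_error(scenario_config(inlet_velocity = -1), "inlet_velocity")
  expect_error(scenario_config(snapshot_times = c(1, 99)), "snapshot_times")
  expect_error(solver_settings(cfl_limit = 1.5), "cfl_limit")
})

test_that("unit suffixes are normalized to SI on load", {
  expect_equal(parse_quantity("5 mm/s", "velocity"), 0.005)
  expect_equal(parse_quantity("3 mm", "length"), 0.003)
  expect_equal(parse_quantity("36 C", "temperature"), 309.15)
  expect_equal(parse_quantity("85 C", "temperature"), 358.15)
  expect_equal(parse_quantity(358, "temperature"), 358)
  expect_error(parse_quantity("5 furlongs", "length"), "unit")
  cfg <- scenario_config(inlet_velocity = "5 mm/s", pullback_velocity = "2 mm/s",
                         electrode_temperature = "85 C")
  expect_equal(cfg$inlet_velocity, 5e-3)
  expect_equal(cfg$pullback_velocity, 2e-3)
  expect_equal(cfg$electrode_temperature, 358.15)
})

test_that("Reynolds number follows rho U D / mu and its scaling laws", {
  expect_equal(reynolds_number(0, 0.003, 1050, 0.0035), 0)
  expect_equal(reynolds_number(0.023, 0.003, 1050, 0.0035), 20.7)
  expect_equal(reynolds_number(0.040, 0.003, 1050, 0.0035), 36.0)
  expect_error(reynolds_number(0.01, 0.003, 1050, 0), "mu")
  # linear in U and D, inverse in mu
  set.seed(7)
  for (i in 1:20) {
    U <- runif(1, 1e-4, 1); D <- runif(1, 1e-4, 0.01)
    rho <- runif(1, 900, 1200); mu <- runif(1, 1e-4, 0.2)
    a <- runif(1, 0.1, 10)
    base <- reynolds_number(U, D, rho, mu)
    expect_equal(reynolds_number(a * U, D, rho, mu), a * base)
    expect_equal(reynolds_number(U, a * D, rho, mu), a * base)
    expect_equal(reynolds_number(U, D, rho, a * mu), base / a)
  }
})

test_that("all studied inlet velocities are laminar; the threshold flips the answer", {
  for (u in c(0, 1, 2.5, 5, 10, 20, 40) * 1e-3)
    expect_true(assert_laminar(scenario_config(inlet_velocity = u)))
  # Re = 2301 requires U = 2301 mu / (rho D)
  u_crit <- 2301 * 0.0035 / (1050 * 0.003)
  expect_false(assert_laminar(scenario_config(inlet_velocity = u_crit)))
  expect_true(assert_laminar(scenario_config(inlet_velocity = 0)))
})

test_that("scenario files round-trip exactly, and matrix files expand to the cross product", {
  cfg <- scenario_config(inlet_velocity = "2.5 mm/s", pullback_velocity = "1 mm/s",
                         duration = 7)
  f <- tempfile(fileext = ".yaml")
  write_scenario(cfg, f)
  cfg2 <- read_scenario(f)
  expect_equal(unclass(cfg2), unclass(cfg))
  fm <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(U_list = list("0 mm/s", "5 mm/s", "10 mm/s"),
                        V_list = list("1 mm/s", "2 mm/s"),
                        duration = 7), fm)
  cfgs <- read_scenario_matrix(fm)
  expect_length(cfgs, 6)
  expect_setequal(vapply(cfgs, function(c) c$inlet_velocity, numeric(1)),
                  rep(c(0, 5e-3, 10e-3), 2))
})
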