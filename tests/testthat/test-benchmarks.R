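test_that("Poiseuille fixture: centreline, no-slip and disc-mean velocity", {
  fx <- poiseuille_fixture(R = 1.5e-3, U = 5e-3)
  expect_equal(fx$u_z(0), 2 * 5e-3)
  expect_equal(fx$u_z(1.5e-3), 0)
  # volumetric mean over the disc equals U (midpoint quadrature)
  r <- seq(0, 1.5e-3, length.out = 20001)
  rm <- (r[-1] + r[-length(r)]) / 2
  mean_u <- sum(fx$u_z(rm) * 2 * pi * rm * diff(r)) / (pi * (1.5e-3)^2)
  expect_equal(mean_u, 5e-3, tolerance = 1e-6)
})

test_that("conduction fixture: boundary and initial limits, default wall diffusivity", {
  fx <- conduction_fixture()
  expect_equal(fx$alpha, 0.56 / (1120 * 3780))
  expect_equal(fx$T(0, 1), 358)
  expect_equal(fx$T(0.01, 1e-12), 309.15, tolerance = 1e-6)
  expect_equal(fx$T(1, 1), 309.15, tolerance = 1e-9)
})

test_that("manufactured fields verify the operator orders of accuracy", {
  # constant target: the diffusion operator returns zero
  props <- material_properties()
  mesh <- rfavein:::new_axisym_mesh(seq(10e-3, 14e-3, length.out = 17),
                                    seq(0, 20e-3, length.out = 33),
                                    rep(2L, 16))
  lap <- rfavein:::heat_laplacian(mesh, props)
  expect_equal(max(abs(lap$L %*% rep(5, 16 * 32))), 0, tolerance = 1e-12)
  # smooth 2-D target: second order in h
  slope <- rfavein:::diffusion_order_slope(c(16L, 32L, 64L))
  expect_gt(slope, 1.85)
  # upwind advection: exact for a linear-in-z field, first order on a smooth one
  fx <- manufactured_solution_fixture()
  adv_err <- function(n) {
    m <- rfavein:::new_axisym_mesh(seq(fx$r0, fx$r1, length.out = n + 1L),
                                   seq(0, fx$Lz, length.out = 2L * n + 1L),
                                   rep(1L, n))
    u0 <- 1e-3
    fl <- plug_flow(m, u0)
    Tm <- outer(m$r_c, m$z_c, fx$T) + 320
    rate <- rfavein:::advect_energy(Tm, fl, m, props, 320, U = 0) /
      (props$rho_b * props$c_pb * m$vol)
    exact <- -u0 * outer(m$r_c, m$z_c, fx$dTdz)
    interior <- 2:(2L * n - 1L)
    max(abs((rate - exact)[, interior]))
  }
  # linear field: upwind differences are exact
  m <- rfavein:::new_axisym_mesh(seq(fx$r0, fx$r1, length.out = 9),
                                 seq(0, 20e-3, length.out = 41),
                                 rep(1L, 8))
  Tl <- matrix(300 + 1000 * m$z_c, m$nr, m$nz, byrow = TRUE)
  rate <- rfavein:::advect_energy(Tl, plug_flow(m, 1e-3), m, props, 300, U = 0) /
    (props$rho_b * props$c_pb * m$vol)
  expect_equal(max(abs(rate[, 2:(m$nz - 1L)] + 1e-3 * 1000)), 0, tolerance = 1e-9)
  # smooth field: error halves with the grid (first order)
  e1 <- adv_err(16L); e2 <- adv_err(32L)
  expect_gt(e1 / e2, 1.7)
})

test_that("the scenario suite covers the study matrix and validates", {
  suite <- scenario_suite()
  expect_length(suite, 7 + 2 + 8)
  ids <- vapply(suite, function(cfg) cfg$id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  for (cfg in suite) expect_s3_class(validate_config(cfg), "scenario_config")
  U <- vapply(suite[1:7], function(cfg) cfg$inlet_velocity, numeric(1))
  expect_equal(U, c(0, 1, 2.5, 5, 10, 20, 40) * 1e-3)
  expect_true(all(vapply(suite[1:7], function(cfg) cfg$pullback_velocity, numeric(1)) == 0))
})

test_that("the reduced smoke suite runs end-to-end", {
  smoke <- scenario_suite(reduced = TRUE)
  expect_gte(length(smoke), 2)
  out <- run_scenario(smoke[[1]], out_dir = NULL)
  expect_length(out$metrics, 2)
  expect_gt(out$metrics[[2]]$influenced_fraction, 0)
})

test_that("the full verification suite passes", {
  v <- run_verification()
  expect_true(all(v$pass), info = paste(capture.output(print(v)), collapse = "\n"))
})
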