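props <- material_properties()
geom <- vein_geometry()

test_that("Carreau-Yasuda viscosity hits its limits and the independent scalar form", {
  cy <- carreau_yasuda()
  expect_equal(carreau_yasuda_viscosity(0, cy), 0.16)
  expect_equal(carreau_yasuda_viscosity(1e12, cy), 0.0035, tolerance = 1e-4)
  # independent evaluation at gamma = 1/lambda
  expect_equal(carreau_yasuda_viscosity(1 / 8.2, cy),
               0.0035 + (0.16 - 0.0035) * 2^((0.2128 - 1) / 0.64))
  g <- 10^seq(-3, 5, length.out = 200)
  mu <- carreau_yasuda_viscosity(g, cy)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= cy$mu_inf & mu <= cy$mu_0))
  expect_error(carreau_yasuda_viscosity(-1, cy), "non-negative")
})

test_that("no forcing gives an identically zero field", {
  mesh <- build_mesh(geom, nr = 19, nz = 40)
  fl <- solve_flow(mesh, props, newtonian_cy(), U = 0)
  expect_equal(max(abs(fl$uz)), 0)
  expect_equal(max(abs(fl$ur)), 0)
})

test_that("Newtonian pipe flow reproduces Poiseuille and conserves mass exactly", {
  mesh <- build_mesh(geom, nr = 19, nz = 60)
  U <- 5e-3
  fl <- solve_flow(mesh, props, newtonian_cy(), U = U)
  jm <- 30
  uzc <- (fl$uz[, jm] + fl$uz[, jm + 1]) / 2
  lum <- seq_len(mesh$i_lumen)
  exact <- 2 * U * (1 - (mesh$r_c[lum] / 1.5e-3)^2)
  # centreline within 2 % of 2U
  expect_equal(uzc[1], 2 * U, tolerance = 0.02)
  expect_lt(max(abs(uzc[lum] - exact)) / (2 * U), 0.02)
  # axial volume flux through every cross-section equals pi R^2 U
  Q0 <- pi * (1.5e-3)^2 * U
  Q <- colSums(mesh$Az * fl$uz)
  expect_lt(max(abs(Q - Q0)) / Q0, 1e-6)
  expect_lt(fl$div_rel, 1e-8)
  # shear rate matches |du/dr| = 4 U r / R^2 away from the boundary rings
  gam <- shear_rate(fl, mesh)
  inner <- 2:(mesh$i_lumen - 2L)
  expect_lt(max(abs(gam[inner, jm] - 4 * U * mesh$r_c[inner] / (1.5e-3)^2)) /
              (4 * U / 1.5e-3), 0.02)
})

test_that("velocity error against the analytic profile decreases under refinement", {
  U <- 5e-3
  errs <- vapply(c(10L, 19L, 38L), function(nr) {
    mesh <- build_mesh(geom, nr = nr, nz = 40)
    fl <- solve_flow(mesh, props, newtonian_cy(), U = U)
    jm <- 20
    uzc <- (fl$uz[, jm] + fl$uz[, jm + 1]) / 2
    lum <- seq_len(mesh$i_lumen)
    exact <- 2 * U * (1 - (mesh$r_c[lum] / 1.5e-3)^2)
    max(abs(uzc[lum] - exact)) / (2 * U)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("flux is conserved through every cross-section with an electrode present", {
  mesh <- build_mesh(geom, nr = 19, nz = 60)
  U <- 5e-3
  es <- electrode_state(20e-3, 0, 358)
  fl <- solve_flow(mesh, props, carreau_yasuda(), U = U, electrode = es)
  Q0 <- pi * (1.5e-3)^2 * U
  Q <- colSums(mesh$Az * fl$uz)
  expect_lt(max(abs(Q - Q0)) / Q0, 1e-6)
  expect_lt(fl$div_rel, 1e-8)
  # effective viscosity bounded by the Carreau-Yasuda limits
  expect_true(all(fl$mu_eff >= 0.0035 - 1e-12 & fl$mu_eff <= 0.16 + 1e-12))
  expect_length(fl$residuals, fl$iterations)
})

test_that("Newtonian annular flow around a centred rod matches the closed form", {
  geomA <- vein_geometry(electrode_start_z = 0, electrode_length = 60e-3)
  mesh <- build_mesh(geomA, nr = 19, nz = 60)
  fl <- solve_flow(mesh, props, newtonian_cy(), U = 5e-3,
                   electrode = electrode_state(0, 0, 358))
  fx <- annular_poiseuille_fixture(ri = 0.2e-3, R = 1.5e-3, U = 5e-3)
  ann <- (mesh$i_core + 1L):mesh$i_lumen
  jm <- 30
  uzc <- (fl$uz[, jm] + fl$uz[, jm + 1]) / 2
  expect_lt(max(abs(uzc[ann] - fx$u_z(mesh$r_c[ann]))) /
              max(fx$u_z(mesh$r_c[ann])), 0.03)
})

test_that("shear rate is zero for plug flow and for a field at rest", {
  mesh <- build_mesh(geom, nr = 19, nz = 40)
  fl <- plug_flow(mesh, 5e-3)
  gam <- shear_rate(fl, mesh)
  interior <- 2:(mesh$nr - 1L)
  expect_equal(max(gam[interior, 2:(mesh$nz - 1L)]), 0)
  fl0 <- plug_flow(mesh, 0)
  expect_equal(max(shear_rate(fl0, mesh)), 0)
})

test_that("a moving electrode in stagnant blood stirs the lumen", {
  mesh <- build_mesh(geom, nr = 19, nz = 60)
  es <- electrode_state(20e-3, 1e-3, 358)
  fl <- solve_flow(mesh, props, carreau_yasuda(), U = 0, electrode = es)
  # the electrode surface carries -V and displaces fluid
  expect_lt(min(fl$uz), -0.9e-3)
  expect_gt(max(abs(fl$ur)), 0)
  expect_lt(fl$div_rel, 1e-8)
})
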