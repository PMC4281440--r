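mesh <- build_mesh(vein_geometry(), nr = 19, nz = 60)
props <- material_properties()

test_that("interface profile extraction: flat and z-dependent fields", {
  Tf <- temperature_field(309.15, mesh)
  prof <- extract_interface_profile(Tf, mesh, props)
  expect_equal(prof$T, rep(309.15, mesh$nz))
  expect_true(all(diff(prof$z) > 0))
  fz <- 310 + 5 * sin(2 * pi * mesh$z_c / 60e-3)
  Tf2 <- temperature_field(matrix(fz, mesh$nr, mesh$nz, byrow = TRUE), mesh)
  prof2 <- extract_interface_profile(Tf2, mesh, props)
  expect_equal(prof2$T, fz)
})

test_that("peak location: tie-break at the smallest z and a Gaussian bump at 25 mm", {
  flat <- structure(list(z = mesh$z_c, T = rep(312, mesh$nz)),
                    class = "interface_profile")
  pk <- peak_interface_temperature(flat)
  expect_equal(pk$z_peak, mesh$z_c[1])
  expect_equal(pk$T_peak, 312)
  bump <- structure(list(z = mesh$z_c,
                         T = 310 + 8 * exp(-((mesh$z_c - 25e-3) / 4e-3)^2)),
                    class = "interface_profile")
  pk2 <- peak_interface_temperature(bump)
  expect_equal(pk2$z_peak, mesh$z_c[which.min(abs(mesh$z_c - 25e-3))])
  expect_error(peak_interface_temperature(list(z = numeric(0), T = numeric(0))),
               "empty")
})

test_that("influenced fraction: trivial fields, half-domain construction, monotone sweep", {
  expect_equal(influenced_fraction(temperature_field(309.15, mesh), mesh, 310.15), 0)
  expect_equal(influenced_fraction(temperature_field(358, mesh), mesh, 310.15), 1)
  # above threshold exactly for z < 30 mm: volume-weighted fraction 1/2
  Tm <- matrix(309.15, mesh$nr, mesh$nz)
  Tm[, mesh$z_c < 30e-3] <- 320
  expect_equal(influenced_fraction(temperature_field(Tm, mesh), mesh, 310.15), 0.5)
  expect_equal(influenced_fraction(temperature_field(Tm, mesh), mesh, 310.15,
                                   weight = "area"), 0.5)
  # sweep is non-increasing in the threshold
  Tm2 <- matrix(309.15 + 49 * runif(mesh$nr * mesh$nz), mesh$nr, mesh$nz)
  sw <- influenced_sweep(temperature_field(Tm2, mesh), mesh,
                         thresholds = seq(309.5, 357, length.out = 30))
  expect_true(all(diff(sw$fraction) <= 0))
})

test_that("wall absorbed energy matches the closed-form heat capacity", {
  expect_equal(wall_absorbed_energy(temperature_field(309.15, mesh), mesh, props), 0)
  Tm <- matrix(309.15, mesh$nr, mesh$nz)
  Tm[mesh$region == 2L] <- 310.15
  V_wall <- pi * ((1.9e-3)^2 - (1.5e-3)^2) * 60e-3
  expect_equal(wall_absorbed_energy(temperature_field(Tm, mesh), mesh, props),
               1120 * 3780 * V_wall, tolerance = 1e-12)
})

test_that("metrics report respects its internal ordering invariants", {
  cfg <- scenario_config(inlet_velocity = 0, numerics = small_numerics())
  Tm <- matrix(309.15 + 40 * exp(-((matrix(mesh$z_c, mesh$nr, mesh$nz,
                                           byrow = TRUE) - 25e-3) / 5e-3)^2) *
                 exp(-matrix(mesh$r_c, mesh$nr, mesh$nz) / 1e-3), mesh$nr, mesh$nz)
  mr <- metrics_report(temperature_field(Tm, mesh, 7), mesh, cfg)
  expect_lte(mr$irreversible_fraction_323K, mr$damage_fraction_313K)
  expect_gte(mr$influenced_fraction, mr$damage_fraction_313K)
  expect_true(mr$influenced_fraction >= 0 && mr$influenced_fraction <= 1)
  expect_gte(mr$max_domain_T, mr$peak_interface_T)
})
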