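#' Analytic Poiseuille fixture
#'
#' Fully developed laminar pipe flow with mean velocity `U`:
#' \eqn{u_z(r) = 2U(1 - r^2/R^2)}, \eqn{u_r = 0}, with the matching
#' pressure gradient \eqn{dp/dz = -8\mu U/R^2}.  Serves as the flow-solver
#' oracle in the Newtonian limit.
#'
#' @param R pipe radius (m). @param U mean velocity (m/s).
#' @param mu dynamic viscosity (kg/(m s)).
#' @return an `analytic_fixture` with evaluators `u_z(r)`,
#'   `shear_rate(r)` (\eqn{4Ur/R^2}) and the pressure gradient `dpdz`.
#' @export
poiseuille_fixture <- function(R = 1.5e-3, U = 5e-3, mu = 0.0035) {
  stopifnot(R > 0, U >= 0, mu > 0)
  structure(list(
    name = "poiseuille",
    R = R, U = U, mu = mu,
    u_z = function(r) 2 * U * (1 - (r / R)^2),
    shear_rate = function(r) 4 * U * r / R^2,
    dpdz = -8 * mu * U / R^2,
    tolerance = 0.02), class = "analytic_fixture")
}

#' Annular Poiseuille fixture
#'
#' Steady axial flow between a stationary inner rod (radius `ri`) and the
#' vessel wall (radius `R`), normalized to a prescribed mean velocity over
#' the annulus.  Oracle for the Newtonian flow around a full-length
#' centred electrode.
#'
#' @param ri inner (rod) radius (m). @param R outer radius (m).
#' @param U mean velocity over the annulus (m/s).
#' @return an `analytic_fixture` with evaluator `u_z(r)`.
#' @export
annular_poiseuille_fixture <- function(ri = 0.2e-3, R = 1.5e-3, U = 5e-3) {
  stopifnot(0 < ri, ri < R, U >= 0)
  # u(r) = A [ (R^2 - r^2) + (R^2 - ri^2) ln(r/R) / ln(R/ri) ]; normalize A
  shape <- function(r) (R^2 - r^2) + (R^2 - ri^2) * log(r / R) / log(R / ri)
  # mean over annulus: (2 / (R^2 - ri^2)) int_ri^R shape(r) r dr
  nq <- 4096
  rq <- seq(ri, R, length.out = nq)
  mean_shape <- 2 / (R^2 - ri^2) * sum(shape(rq) * rq) * (R - ri) / nq
  A <- U / mean_shape
  structure(list(name = "annular_poiseuille", ri = ri, R = R, U = U,
                 u_z = function(r) A * shape(r),
                 tolerance = 0.03), class = "analytic_fixture")
}

#' Semi-infinite transient conduction fixture
#'
#' Sudden surface-temperature step on a semi-infinite solid:
#' \deqn{T(x,t) = T_s + (T_i - T_s)\,\mathrm{erf}\!\big(x / (2\sqrt{\alpha t})\big).}
#' Oracle for the implicit diffusion step; the default diffusivity is the
#' vein wall value \eqn{\alpha_w = K_w/(\rho_w C_{pw}) \approx 1.32\times
#' 10^{-7}} m^2/s.
#'
#' @param alpha thermal diffusivity (m^2/s).
#' @param T_s surface temperature (K). @param T_i initial temperature (K).
#' @return an `analytic_fixture` with evaluator `T(x, t)`.
#' @export
conduction_fixture <- function(alpha = 0.56 / (1120 * 3780),
                               T_s = 358, T_i = 309.15) {
  stopifnot(alpha > 0)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  structure(list(name = "semi_infinite_conduction",
                 alpha = alpha, T_s = T_s, T_i = T_i,
                 T = function(x, t) {
                   if (t <= 0) return(ifelse(x > 0, T_i, T_s))
                   T_s + (T_i - T_s) * erf(x / (2 * sqrt(alpha * t)))
                 },
                 tolerance = 0.01), class = "analytic_fixture")
}

#' Composite-cylinder steady conduction fixture
#'
#' Steady radial conduction through two concentric material layers (blood
#' from `r_in` to `r_mid`, wall from `r_mid` to `r_out`) with fixed inner
#' and outer temperatures.  The temperature is logarithmic within each
#' layer and the interface value follows from flux continuity.  Oracle for
#' the conjugate (harmonic-mean) interface treatment.
#'
#' @param r_in,r_mid,r_out layer radii (m).
#' @param k_in,k_out layer conductivities (W/(m K)).
#' @param T_in,T_out boundary temperatures (K).
#' @return an `analytic_fixture` with evaluator `T(r)` and the interface
#'   temperature `T_interface`.
#' @export
two_layer_fixture <- function(r_in = 0.2e-3, r_mid = 1.5e-3, r_out = 1.9e-3,
                              k_in = 0.492, k_out = 0.56,
                              T_in = 358, T_out = 309.15) {
  stopifnot(r_in < r_mid, r_mid < r_out, k_in > 0, k_out > 0)
  R1 <- log(r_mid / r_in) / (2 * pi * k_in)    # thermal resistances per length
  R2 <- log(r_out / r_mid) / (2 * pi * k_out)
  Q <- (T_in - T_out) / (R1 + R2)              # W per metre of axis
  T_interface <- T_in - Q * R1
  structure(list(name = "two_layer_cylinder",
                 r_in = r_in, r_mid = r_mid, r_out = r_out,
                 k_in = k_in, k_out = k_out, T_in = T_in, T_out = T_out,
                 Q_per_length = Q, T_interface = T_interface,
                 T = function(r) ifelse(r <= r_mid,
                                        T_in - Q * log(r / r_in) / (2 * pi * k_in),
                                        T_interface - Q * log(r / r_mid) / (2 * pi * k_out)),
                 tolerance = 0.005), class = "analytic_fixture")
}

#' Manufactured smooth-field fixture for operator verification
#'
#' Supplies a smooth product-of-cosines temperature field on an annulus,
#' compatible with the solver's zero-flux boundaries, together with its
#' exact axisymmetric Laplacian and axial gradient.  Used to measure the
#' discrete diffusion operator's second-order and the upwind advection
#' operator's first-order convergence under mesh refinement.
#'
#' @param mode_counts integer pair: number of half-waves radially and
#'   axially.
#' @param r0,r1 radial extent (m). @param Lz axial extent (m).
#' @return an `analytic_fixture` with evaluators `T(r, z)`,
#'   `laplacian(r, z)` and `dTdz(r, z)`.
#' @export
manufactured_solution_fixture <- function(mode_counts = c(1L, 2L),
                                          r0 = 10e-3, r1 = 14e-3, Lz = 20e-3) {
  kr <- mode_counts[1] * pi / (r1 - r0)
  kz <- mode_counts[2] * pi / Lz
  Tfun <- function(r, z) cos(kr * (r - r0)) * cos(kz * z)
  structure(list(
    name = "manufactured_cosine", r0 = r0, r1 = r1, Lz = Lz,
    T = Tfun,
    # axisymmetric Laplacian: T_rr + T_r / r + T_zz
    laplacian = function(r, z)
      (-kr^2 * cos(kr * (r - r0)) - kr * sin(kr * (r - r0)) / r) * cos(kz * z) -
      kz^2 * Tfun(r, z),
    dTdz = function(r, z) -kz * cos(kr * (r - r0)) * sin(kz * z),
    tolerance = NA_real_), class = "analytic_fixture")
}

#' The study's scenario matrix
#'
#' The stationary-electrode inlet-velocity sweep (7 scenarios), the
#' stagnant-blood pullback pair (V = 1 and 2 mm/s), and the low-velocity
#' cross `U in {0, 1, 2.5, 5} x V in {1, 2}` mm/s used for the interfacial
#' profiles, all at 7 s.  With `reduced = TRUE`, returns quick smoke-test
#' variants (short domain, 1 s duration, coarse grid) for continuous
#' testing.
#'
#' @param reduced return the reduced smoke-test suite instead.
#' @return list of [scenario_config()] objects.
#' @export
scenario_suite <- function(reduced = FALSE) {
  if (reduced) {
    geom <- vein_geometry(domain_length = 20e-3, electrode_length = 5e-3,
                          electrode_start_z = 8e-3)
    num <- solver_settings(nr = 10L, nz = 40L, dt_max = 10e-3)
    combos <- list(c(0, 1e-3), c(5e-3, 2e-3))
    return(lapply(combos, function(uv)
      scenario_config(inlet_velocity = uv[1], pullback_velocity = uv[2],
                      duration = 1, snapshot_times = c(0.5, 1),
                      geometry = geom, numerics = num,
                      id = sprintf("smoke_U%g_V%g", uv[1] * 1e3, uv[2] * 1e3))))
  }
  U_all <- c(0, 1, 2.5, 5, 10, 20, 40) * 1e-3
  stationary <- lapply(U_all, function(u)
    scenario_config(inlet_velocity = u, pullback_velocity = 0,
                    id = sprintf("stationary_U%g", u * 1e3)))
  stagnant <- lapply(c(1e-3, 2e-3), function(v)
    scenario_config(inlet_velocity = 0, pullback_velocity = v,
                    id = sprintf("stagnant_V%g", v * 1e3)))
  cross <- list()
  for (v in c(1e-3, 2e-3))
    for (u in c(0, 1, 2.5, 5) * 1e-3)
      cross[[length(cross) + 1L]] <-
        scenario_config(inlet_velocity = u, pullback_velocity = v,
                        id = sprintf("cross_U%g_V%g", u * 1e3, v * 1e3))
  c(stationary, stagnant, cross)
}

#' Run the analytic verification suite
#'
#' Executes the solver-against-oracle comparisons at reduced scale:
#' Poiseuille centreline and profile, annular Poiseuille around a
#' full-length rod, semi-infinite transient conduction, composite-cylinder
#' steady conduction with interface-flux continuity, and the
#' diffusion-operator order-of-accuracy study.  Returns a pass/fail table
#' and writes a JSON report when `out` is given.
#'
#' @param out optional path for a JSON report.
#' @param quick use the coarsest settings (default; there is no slow mode
#'   that changes the checks, only the grids).
#' @return data.frame with columns `check`, `value`, `tolerance`, `pass`.
#' @export
run_verification <- function(out = NULL, quick = TRUE) {
  checks <- list()
  add <- function(name, value, tol) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, value = value, tolerance = tol, pass = value <= tol)

  props <- material_properties()
  cyN <- carreau_yasuda(mu_inf = 0.0035, mu_0 = 0.0035 * (1 + 1e-9))

  # Poiseuille
  fx <- poiseuille_fixture()
  mesh <- build_mesh(vein_geometry(), nr = 19, nz = 60)
  fl <- solve_flow(mesh, props, cyN, U = fx$U)
  jm <- mesh$nz %/% 2
  uzc <- (fl$uz[, jm] + fl$uz[, jm + 1]) / 2
  lum <- seq_len(mesh$i_lumen)
  err <- max(abs(uzc[lum] - fx$u_z(mesh$r_c[lum]))) / (2 * fx$U)
  add("poiseuille_profile_rel_err", err, fx$tolerance)
  add("poiseuille_divergence_rel", fl$div_rel, 1e-8)

  # annular Poiseuille around a full-length rod
  geomA <- vein_geometry(electrode_start_z = 0, electrode_length = 60e-3)
  meshA <- build_mesh(geomA, nr = 19, nz = 60)
  esA <- electrode_state(0, 0, 358)
  flA <- solve_flow(meshA, props, cyN, U = 5e-3, electrode = esA)
  fxA <- annular_poiseuille_fixture()
  # mean inlet velocity over the annulus equals the imposed U
  ann <- (meshA$i_core + 1L):meshA$i_lumen
  uzcA <- (flA$uz[, jm] + flA$uz[, jm + 1]) / 2
  errA <- max(abs(uzcA[ann] - fxA$u_z(meshA$r_c[ann]))) / max(fxA$u_z(meshA$r_c[ann]))
  add("annular_poiseuille_rel_err", errA, fxA$tolerance)

  # semi-infinite conduction (wall properties), planar slab limit
  fxC <- conduction_fixture()
  errC <- erf_conduction_error(fxC, props)
  add("erf_conduction_rel_err", errC, fxC$tolerance)

  # two-layer steady conduction
  res2 <- two_layer_error(props)
  add("two_layer_interface_rel_err", res2$T_err, res2$fixture$tolerance)
  add("two_layer_flux_mismatch_rel", res2$flux_mismatch, 1e-8)

  # diffusion operator order of accuracy
  slope <- diffusion_order_slope()
  add("diffusion_operator_order_deficit", max(0, 2 - slope), 0.15)

  res <- do.call(rbind, checks)
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}

# Transient 1-D (radial) conduction against the erf solution on a thin
# large-radius annulus, where curvature is negligible.  The innermost ring
# is a Dirichlet mask, so x is measured from that ring's centre.
erf_conduction_error <- function(fx = conduction_fixture(),
                                 props = material_properties(),
                                 t_final = 4, dt = 0.01,
                                 region = REGION_WALL) {
  R0 <- 1   # 1 m base radius: planar to ~0.25%
  thick <- 5e-3
  nr <- 160L
  mesh <- new_axisym_mesh(seq(R0, R0 + thick, length.out = nr + 1L),
                          seq(0, 2e-3, length.out = 5L),
                          rep(region, nr))
  dmask <- matrix(FALSE, nr, mesh$nz); dmask[1, ] <- TRUE
  cache <- make_heat_cache(mesh, props, dmask, U = 0, dt = dt,
                           body_T = fx$T_i, elec_T = fx$T_s)
  Tm <- matrix(fx$T_i, nr, mesh$nz)
  nsteps <- round(t_final / dt)
  for (s in seq_len(nsteps)) {
    outp <- heat_step_core(Tm, NULL, mesh, props, cache, 1)
    Tm <- outp$T
  }
  x <- mesh$r_c - mesh$r_c[1]
  exact <- fx$T(x, t_final)
  interior <- x > 0 & x < 0.8 * thick
  max(abs(Tm[interior, 1] - exact[interior])) / abs(fx$T_s - fx$T_i)
}

# Steady composite-cylinder conduction with Dirichlet inner core and outer
# boundary; compares the discrete interface temperature and the
# interface-flux jump against the closed form.  The discrete Dirichlet
# surface sits at the centre of the outermost masked ring, so the closed
# form is evaluated with that radius as its inner boundary.
two_layer_error <- function(props = material_properties(),
                            T_in = 358, T_out = 309.15) {
  geom <- vein_geometry(electrode_start_z = 0, electrode_length = 60e-3)
  mesh <- build_mesh(geom, nr = 38, nz = 8)
  dmask <- matrix(FALSE, mesh$nr, mesh$nz)
  dmask[seq_len(mesh$i_core), ] <- TRUE
  fx <- two_layer_fixture(r_in = mesh$r_c[mesh$i_core],
                          r_mid = geom$lumen_radius,
                          r_out = geom$lumen_radius + geom$wall_thickness,
                          k_in = props$k_b, k_out = props$k_w,
                          T_in = T_in, T_out = T_out)
  Tf <- solve_steady_temperature(mesh, props, dmask, T_in, outer_T = T_out)
  chk <- interface_flux_check(Tf, mesh, props)
  prof <- extract_interface_profile(Tf, mesh, props)
  list(T_err = abs(mean(prof$T) - fx$T_interface) / abs(T_in - T_out),
       flux_mismatch = chk$rel_mismatch,
       grad_ratio = {
         # one-sided gradient ratio across the interface = k_wall/k_blood
         iR <- mesh$i_lumen
         gl <- (chk$T_face - Tf$T[iR, ]) / (mesh$r_faces[iR + 1] - mesh$r_c[iR])
         gw <- (Tf$T[iR + 1, ] - chk$T_face) / (mesh$r_c[iR + 1] - mesh$r_faces[iR + 1])
         mean(gl / gw)
       },
       fixture = fx)
}

# L2 convergence slope of the discrete diffusion operator against the
# manufactured cosine field on an annulus (interior cells).
diffusion_order_slope <- function(ns = c(16L, 32L, 64L)) {
  fx <- manufactured_solution_fixture()
  props <- material_properties()
  errs <- vapply(ns, function(n) {
    nr <- n; nz <- 2L * n
    mesh <- new_axisym_mesh(seq(fx$r0, fx$r1, length.out = nr + 1L),
                            seq(0, fx$Lz, length.out = nz + 1L),
                            rep(REGION_WALL, nr))
    lap <- heat_laplacian(mesh, props)
    Tm <- outer(mesh$r_c, mesh$z_c, fx$T)
    LT <- matrix(as.numeric(lap$L %*% as.numeric(Tm)), nr, nz)
    # L T approximates -k * laplacian * volume (conductance convention)
    exact <- -props$k_w * outer(mesh$r_c, mesh$z_c, fx$laplacian) * mesh$vol
    interior <- matrix(FALSE, nr, nz)
    interior[3:(nr - 2L), 3:(nz - 2L)] <- TRUE
    sqrt(mean(((LT - exact)[interior] / mesh$vol[interior])^2))
  }, numeric(1))
  fitlm <- stats::lm(log(errs) ~ log(1 / ns))
  as.numeric(stats::coef(fitlm)[2])
}
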