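#' Temperature field container
#'
#' @param T `nr x nz` matrix of cell-centred temperatures (K), or a scalar
#'   to fill uniformly.
#' @param mesh the mesh the field lives on.
#' @param time simulation time (s).
#' @return an object of class `temperature_field`.
#' @export
temperature_field <- function(T, mesh, time = 0) {
  if (length(T) == 1L) T <- matrix(T, mesh$nr, mesh$nz)
  stopifnot(nrow(T) == mesh$nr, ncol(T) == mesh$nz)
  structure(list(T = T, time = time), class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field t = %.3g s, T in [%.2f, %.2f] K>\n",
              x$time, min(x$T), max(x$T)))
  invisible(x)
}

# Per-ring thermal properties: blood values in the lumen, wall values in
# the wall (region-dependent conjugate formulation).
ring_props <- function(mesh, props) {
  lum <- mesh$region_ring == REGION_LUMEN
  list(k = ifelse(lum, props$k_b, props$k_w),
       rhoc = ifelse(lum, props$rho_b * props$c_pb, props$rho_w * props$c_pw))
}

# Conductance Laplacian of the conjugate domain: harmonic-mean face
# conductivities across radial material interfaces, optional inlet
# Dirichlet half-links (U > 0), optional outer-wall Dirichlet half-links
# (verification only; the physical outer boundary is adiabatic).
heat_laplacian <- function(mesh, props, U = 0, outer_dirichlet = FALSE) {
  nr <- mesh$nr; nz <- mesh$nz; n <- nr * nz
  rp <- ring_props(mesh, props)
  kr <- rp$k
  IC <- matrix(seq_len(n), nr, nz)
  dvec <- numeric(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  # axial links (regions are radial bands, so k is single-valued per link)
  if (nz > 1L) {
    Gz <- kr * mesh$Az / mesh$dz                       # length nr
    a <- IC[, -nz, drop = FALSE]; bcol <- IC[, -1, drop = FALSE]
    g <- matrix(Gz, nr, nz - 1L)
    ii <- c(ii, a, bcol); jj <- c(jj, bcol, a); xx <- c(xx, -g, -g)
    dvec[a] <- dvec[a] + g; dvec[bcol] <- dvec[bcol] + g
  }
  # radial links with harmonic-mean conductivity across the face
  if (nr > 1L) {
    rf <- mesh$r_faces; rc <- mesh$r_c
    d1 <- rf[2:nr] - rc[-nr]; d2 <- rc[-1] - rf[2:nr]
    Gr <- (2 * pi * rf[2:nr] * mesh$dz) / (d1 / kr[-nr] + d2 / kr[-1])
    a <- IC[-nr, , drop = FALSE]; bcol <- IC[-1, , drop = FALSE]
    g <- matrix(Gr, nr - 1L, nz)
    ii <- c(ii, a, bcol); jj <- c(jj, bcol, a); xx <- c(xx, -g, -g)
    dvec[a] <- dvec[a] + g; dvec[bcol] <- dvec[bcol] + g
  }
  # inlet Dirichlet (body temperature) for lumen cells when blood flows in
  G_in <- numeric(n)
  if (U > 0) {
    lum <- which(mesh$region_ring == REGION_LUMEN)
    G_in[IC[lum, 1]] <- kr[lum] * mesh$Az[lum] / (mesh$dz / 2)
    dvec <- dvec + G_in
  }
  G_out <- numeric(n)
  if (outer_dirichlet) {
    Rb <- max(mesh$r_faces)
    G_out[IC[nr, ]] <- kr[nr] * 2 * pi * Rb * mesh$dz / (Rb - mesh$r_c[nr])
    dvec <- dvec + G_out
  }
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, dvec), dims = c(n, n))
  list(L = L, G_in = G_in, G_out = G_out)
}

# Build the implicit-diffusion machinery for a fixed electrode mask and
# time step: Dirichlet electrode cells eliminated symmetrically and a
# cached Cholesky factor of the implicit matrix.
make_heat_cache <- function(mesh, props, emask, U, dt, body_T, elec_T,
                            q_rf = 0) {
  nr <- mesh$nr; nz <- mesh$nz; n <- nr * nz
  rp <- ring_props(mesh, props)
  rhocV <- matrix(rp$rhoc, nr, nz) * mesh$vol
  lap <- heat_laplacian(mesh, props, U)
  free <- which(!emask)
  dir <- which(emask)
  Lff <- lap$L[free, free, drop = FALSE]
  Lfd <- lap$L[free, dir, drop = FALSE]
  M <- Matrix::Diagonal(x = rhocV[free] / dt) + Lff
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
  s_fd <- Matrix::rowSums(-Lfd)           # total conductance to electrode
  list(ch = ch, Lfd = Lfd, s_fd = s_fd, free = free, dir = dir,
       rhocV = rhocV, G_in = lap$G_in, dt = dt, body_T = body_T,
       elec_T = elec_T, U = U, q_src = q_rf * mesh$vol, emask = emask)
}

# Explicit conservative upwind advection of heat by the staggered flow
# field.  Returns the net advective power (W) received by each cell.
advect_energy <- function(Tm, flow, mesh, props, body_T, U) {
  nr <- mesh$nr; nz <- mesh$nz
  rhoc <- props$rho_b * props$c_pb
  uz <- flow$uz; ur <- flow$ur
  # axial face fluxes
  Fz <- rhoc * matrix(mesh$Az, nr, nz + 1L) * uz
  TW <- cbind(if (U > 0) rep(body_T, nr) else Tm[, 1], Tm)
  TE <- cbind(Tm, Tm[, nz])
  Tup_z <- ifelse(Fz >= 0, TW, TE)
  Hz <- Fz * Tup_z
  # radial face fluxes
  Arf <- 2 * pi * mesh$r_faces * mesh$dz
  Fr <- rhoc * matrix(Arf, nr + 1L, nz) * ur
  TS <- rbind(Tm[1, ], Tm)
  TN <- rbind(Tm, Tm[nr, ])
  Tup_r <- ifelse(Fr >= 0, TS, TN)
  Hr <- Fr * Tup_r
  (Hz[, -1, drop = FALSE] * -1 + Hz[, -(nz + 1L), drop = FALSE]) +
    (Hr[-1, , drop = FALSE] * -1 + Hr[-(nr + 1L), , drop = FALSE])
}

# One advection-diffusion step against a prepared cache.  Returns the new
# temperature matrix plus an energy audit.
heat_step_core <- function(Tm, flow, mesh, props, cache, cfl_limit) {
  dt <- cache$dt
  nr <- mesh$nr; nz <- mesh$nz
  adv <- NULL
  if (!is.null(flow)) {
    umax_z <- max(abs(flow$uz)); umax_r <- max(abs(flow$ur))
    dt_adv <- cfl_limit * min(
      if (umax_z > 0) mesh$dz / umax_z else Inf,
      if (umax_r > 0) min(mesh$dr) / umax_r else Inf)
    if (dt > dt_adv * (1 + 1e-9))
      stop(sprintf("advective CFL violated: dt = %.3g s but dt <= %.3g s required",
                   dt, dt_adv))
    adv <- advect_energy(Tm, flow, mesh, props, cache$body_T, cache$U)
  }
  Tstar <- Tm
  if (!is.null(adv)) Tstar <- Tm + dt * adv / cache$rhocV
  free <- cache$free
  rhs <- (cache$rhocV[free] / dt) * Tstar[free] + cache$q_src[free]
  if (length(cache$dir))
    rhs <- rhs + cache$s_fd * cache$elec_T
  if (cache$U > 0)
    rhs <- rhs + cache$G_in[free] * cache$body_T
  T1f <- as.numeric(Matrix::solve(cache$ch, rhs))
  T1 <- Tm
  T1[free] <- T1f
  T1[cache$dir] <- cache$elec_T
  # energy audit: storage change must equal advective input + electrode and
  # inlet diffusive fluxes (+ any volumetric source), to solver precision
  E0 <- sum(cache$rhocV[free] * Tm[free])
  E1 <- sum(cache$rhocV[free] * T1[free])
  adv_pow <- if (is.null(adv)) 0 else sum(adv[free])
  elec_pow <- if (length(cache$dir)) sum(cache$s_fd * (cache$elec_T - T1f)) else 0
  in_pow <- if (cache$U > 0) sum(cache$G_in[free] * (cache$body_T - T1f)) else 0
  src_pow <- sum(cache$q_src[free])
  resid <- (E1 - E0) - dt * (adv_pow + elec_pow + in_pow + src_pow)
  scale <- max(abs(E1 - E0), dt * abs(elec_pow), dt * abs(adv_pow),
               sum(cache$rhocV[free]) * 1e-12)
  list(T = T1, audit = c(dE = E1 - E0, adv_J = dt * adv_pow,
                         electrode_J = dt * elec_pow, inlet_J = dt * in_pow,
                         residual_rel = resid / scale))
}

#' Advance the conjugate temperature field by one time step
#'
#' Advection (explicit, conservative first-order upwind, blood properties)
#' plus diffusion (implicit, second-order, region-wise conductivity with
#' harmonic-mean face values at the lumen--wall interface).  Electrode
#' cells are Dirichlet at the electrode surface temperature; the inlet is
#' Dirichlet at body temperature when `U > 0` and adiabatic otherwise; the
#' outer wall, the outlet and (for `U = 0`) the inlet carry zero heat
#' flux; the axis is a symmetry boundary.  The discrete maximum principle
#' is asserted after every step.
#'
#' @param Tf a [temperature_field()].
#' @param flow a `flow_field` (or `NULL` for pure conduction).
#' @param mesh the mesh.
#' @param electrode_mask logical `nr x nz` matrix of Dirichlet electrode
#'   cells (may be all-`FALSE`).
#' @param props a [material_properties()].
#' @param cfg the [scenario_config()] supplying temperatures and numerics.
#' @param dt time step (s); must satisfy the advective CFL limit.
#' @return updated [temperature_field()] with an `audit` attribute
#'   carrying the step energy bookkeeping.
#' @export
step_temperature <- function(Tf, flow, mesh, electrode_mask, props, cfg, dt) {
  stopifnot(inherits(Tf, "temperature_field"))
  cache <- make_heat_cache(mesh, props, electrode_mask, cfg$inlet_velocity,
                           dt, cfg$body_temperature, cfg$electrode_temperature,
                           cfg$numerics$q_rf_volumetric)
  out <- heat_step_core(Tf$T, flow, mesh, props, cache, cfg$numerics$cfl_limit)
  check_max_principle(Tf$T, out$T, cfg, any(electrode_mask))
  res <- temperature_field(out$T, mesh, Tf$time + dt)
  attr(res, "audit") <- out$audit
  res
}

# Discrete maximum principle: the new field must stay inside the hull of
# the previous field and the active boundary values.
check_max_principle <- function(T0, T1, cfg, has_electrode, tol = 1e-9) {
  lo <- min(T0)
  hi <- max(T0)
  if (has_electrode) { lo <- min(lo, cfg$electrode_temperature); hi <- max(hi, cfg$electrode_temperature) }
  if (cfg$inlet_velocity > 0) { lo <- min(lo, cfg$body_temperature); hi <- max(hi, cfg$body_temperature) }
  if (min(T1) < lo - tol || max(T1) > hi + tol)
    stop(sprintf("maximum principle violated: T in [%.6f, %.6f], bounds [%.6f, %.6f]",
                 min(T1), max(T1), lo, hi))
  invisible(TRUE)
}

#' Heat-flux continuity across the lumen--wall interface
#'
#' Reconstructs the interface-face temperature from flux continuity (the
#' same harmonic-mean construction the solver uses) and returns the
#' normal-flux jump between the blood-side and wall-side one-sided fluxes
#' at every axial station.
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh (must carry a conforming interface face).
#' @param props a [material_properties()].
#' @return list with `z` (m), blood- and wall-side fluxes `q_lumen`,
#'   `q_wall` (W/m^2, positive outward), the jump `mismatch` and its
#'   maximum relative to the electrode-to-body conductive scale
#'   (`rel_mismatch`).
#' @export
interface_flux_check <- function(Tf, mesh, props) {
  iR <- mesh$i_lumen
  stopifnot(iR >= 1L, iR < mesh$nr)
  rf <- mesh$r_faces[iR + 1L]
  d1 <- rf - mesh$r_c[iR]; d2 <- mesh$r_c[iR + 1L] - rf
  Tl <- Tf$T[iR, ]; Tw <- Tf$T[iR + 1L, ]
  wl <- props$k_b / d1; ww <- props$k_w / d2
  Tface <- (wl * Tl + ww * Tw) / (wl + ww)
  q_l <- props$k_b * (Tl - Tface) / d1
  q_w <- props$k_w * (Tface - Tw) / d2
  scale <- props$k_b * (358 - 309.15) / max(mesh$r_faces)
  list(z = mesh$z_c, q_lumen = q_l, q_wall = q_w, T_face = Tface,
       mismatch = q_l - q_w,
       rel_mismatch = max(abs(q_l - q_w)) / scale)
}

# Steady conduction solve used by the verification fixtures: Dirichlet on
# an arbitrary cell mask and optionally on the outer radial boundary,
# zero-flux elsewhere, optional volumetric source (W/m^3).
solve_steady_temperature <- function(mesh, props, dirichlet_mask,
                                     dirichlet_value, outer_T = NULL,
                                     source = NULL) {
  nr <- mesh$nr; nz <- mesh$nz; n <- nr * nz
  lap <- heat_laplacian(mesh, props, U = 0, outer_dirichlet = !is.null(outer_T))
  b <- numeric(n)
  if (!is.null(outer_T)) b <- b + lap$G_out * outer_T
  if (!is.null(source)) b <- b + as.numeric(source) * as.numeric(mesh$vol)
  free <- which(!dirichlet_mask)
  dir <- which(dirichlet_mask)
  Lff <- lap$L[free, free, drop = FALSE]
  rhs <- b[free]
  if (length(dir)) {
    Lfd <- lap$L[free, dir, drop = FALSE]
    rhs <- rhs + Matrix::rowSums(-Lfd) * dirichlet_value
  }
  Tm <- matrix(NA_real_, nr, nz)
  Tm[free] <- as.numeric(Matrix::solve(Lff, rhs))
  Tm[dir] <- dirichlet_value
  temperature_field(Tm, mesh, time = Inf)
}
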