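#' Carreau-Yasuda effective viscosity
#'
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'   \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' Monotonically non-increasing in the shear rate, bounded between
#' \eqn{\mu_\infty} (infinite shear) and \eqn{\mu_0} (zero shear).
#'
#' @param gamma_dot shear-rate magnitude (1/s), vectorized, `>= 0`.
#' @param cy a [carreau_yasuda()] parameter set.
#' @return effective viscosity (kg/(m s)), same shape as `gamma_dot`.
#' @examples
#' carreau_yasuda_viscosity(0, carreau_yasuda())      # 0.16
#' carreau_yasuda_viscosity(1e9, carreau_yasuda())    # ~0.0035
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, cy = carreau_yasuda()) {
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  cy$mu_inf + (cy$mu_0 - cy$mu_inf) *
    (1 + (cy$lambda * gamma_dot)^cy$a)^((cy$n - 1) / cy$a)
}

# ---- boundary classification -------------------------------------------

# Classify every staggered velocity unknown as Dirichlet (with its value)
# or free, given the solid mask (wall cells + electrode-occupied cells).
# uz faces adjacent to an electrode cell carry the pullback velocity -V;
# all other solid-adjacent faces are no-slip.  The inlet is a uniform
# axial Dirichlet when U > 0 and a closed free-slip plane when U = 0.
flow_bc <- function(mesh, solid, emask, U, V) {
  nr <- mesh$nr; nz <- mesh$nz
  AS <- cbind(FALSE, solid) | cbind(solid, FALSE)          # nr x (nz+1)
  AE <- cbind(FALSE, emask) | cbind(emask, FALSE)
  uzD <- AS
  uzD[, 1] <- TRUE
  uzV <- matrix(0, nr, nz + 1L)
  uzV[AE] <- -V
  fluid_inlet <- !solid[, 1]
  uzV[cbind(which(fluid_inlet), 1L)] <- U
  # both-solid flags per uz column, used for half-cell link distances
  BS <- cbind(solid[, 1, drop = FALSE], solid) & cbind(solid, solid[, nz, drop = FALSE])
  urD <- rbind(TRUE, solid) | rbind(solid, TRUE)           # (nr+1) x nz
  list(uzD = uzD, uzV = uzV, urD = urD, BS = BS)
}

# ---- single linearized (Oseen) solve -----------------------------------

# Assemble and solve the coupled momentum + continuity system with the
# viscosity field and convective mass fluxes lagged from the previous
# Picard iterate.  All unknowns (including Dirichlet faces) are kept in
# the system; Dirichlet unknowns get identity rows, so neighbour links can
# reference them directly.  Pressure is anchored through the outlet
# (traction-free ghost at p = 0).
flow_solve_once <- function(mesh, bc, solid, mu, rho, uz0, ur0, U, V) {
  nr <- mesh$nr; nz <- mesh$nz
  dz <- mesh$dz; dr <- mesh$dr
  rf <- mesh$r_faces; rc <- mesh$r_c
  Az <- mesh$Az                           # length nr
  Arf <- 2 * pi * rf * dz                 # length nr+1
  nuz <- nr * (nz + 1L); nur <- (nr + 1L) * nz; np <- nr * nz
  N <- nuz + nur + np
  IUZ <- matrix(seq_len(nuz), nr, nz + 1L)
  IUR <- matrix(nuz + seq_len(nur), nr + 1L, nz)
  IP <- matrix(nuz + nur + seq_len(np), nr, nz)

  ti <- vector("list", 64L); tj <- ti; tx <- ti; nt <- 0L
  emit <- function(i, j, x) {
    keep <- x != 0
    if (!any(keep)) return(invisible())
    nt <<- nt + 1L
    ti[[nt]] <<- i[keep]; tj[[nt]] <<- j[keep]; tx[[nt]] <<- x[keep]
  }
  b <- numeric(N)

  Az_m <- matrix(Az, nr, nz)

  ## ---------------- axial momentum (uz) ----------------
  Fz <- !bc$uzD
  # diffusion through the two adjacent cells
  aW <- cbind(0, mu * Az_m / dz)
  aE <- cbind(mu * Az_m / dz, 0)
  # radial diffusion through the radial faces bounding the uz column
  if (nr > 1L) {
    mu_rf <- (mu[-nr, , drop = FALSE] + mu[-1, , drop = FALSE]) / 2   # (nr-1) x nz
    mu_c <- cbind(mu_rf[, 1], (mu_rf[, -nz, drop = FALSE] + mu_rf[, -1, drop = FALSE]) / 2,
                  mu_rf[, nz])                                        # (nr-1) x (nz+1)
    dN <- matrix(rc[-1] - rc[-nr], nr - 1L, nz + 1L)
    half <- bc$BS[-1, , drop = FALSE]                 # neighbour column fully solid
    dN[half] <- (matrix(rf[2:nr], nr - 1L, nz + 1L) - matrix(rc[-nr], nr - 1L, nz + 1L))[half]
    ArN <- matrix(2 * pi * rf[2:nr] * dz, nr - 1L, nz + 1L)
    aN <- rbind(mu_c * ArN / dN, 0)                   # rows 1..nr-1 have north links
    dS <- matrix(rc[-1] - rc[-nr], nr - 1L, nz + 1L)
    halfS <- bc$BS[-nr, , drop = FALSE]               # southern column fully solid
    dS[halfS] <- (matrix(rc[-1], nr - 1L, nz + 1L) - matrix(rf[2:nr], nr - 1L, nz + 1L))[halfS]
    aS <- rbind(0, mu_c * ArN / dS)                   # rows 2..nr have south links
  } else {
    aN <- aS <- matrix(0, nr, nz + 1L)
  }
  # upwind convection with lagged fluxes
  Fzc <- rho * Az_m * (uz0[, -(nz + 1L), drop = FALSE] + uz0[, -1, drop = FALSE]) / 2
  Fw <- cbind(0, Fzc)
  Fe <- cbind(Fzc, rho * Az * uz0[, nz + 1L])
  urbar <- cbind(ur0[, 1], (ur0[, -nz, drop = FALSE] + ur0[, -1, drop = FALSE]) / 2, ur0[, nz])
  Frc <- matrix(rho * Arf, nr + 1L, nz + 1L) * urbar  # corner mass fluxes
  Fs <- Frc[1:nr, , drop = FALSE]
  Fn <- Frc[2:(nr + 1L), , drop = FALSE]
  aW <- aW + pmax(Fw, 0); aE <- aE + pmax(-Fe, 0)
  aS <- aS + pmax(Fs, 0); aN <- aN + pmax(-Fn, 0)
  netF <- (Fe - Fw) + (Fn - Fs)
  aP <- aW + aE + aN + aS + netF

  emit(IUZ[Fz], IUZ[Fz], aP[Fz])
  # neighbours beyond the outlet or the radial extremes are NA and are
  # simply not emitted (their upwind inflow value is zero)
  W_idx <- cbind(NA, IUZ[, -(nz + 1L), drop = FALSE])
  E_idx <- cbind(IUZ[, -1, drop = FALSE], NA)
  N_idx <- rbind(IUZ[-1, , drop = FALSE], NA)
  S_idx <- rbind(NA, IUZ[-nr, , drop = FALSE])
  for (dir in list(list(W_idx, aW), list(E_idx, aE), list(N_idx, aN), list(S_idx, aS))) {
    m <- Fz & !is.na(dir[[1]]) & dir[[2]] != 0
    emit(IUZ[m], dir[[1]][m], -dir[[2]][m])
  }
  # pressure gradient; the outlet face sees a ghost p = 0 downstream, so
  # only its upstream link appears
  PW <- cbind(NA, IP); PE <- cbind(IP, NA)
  m <- Fz & !is.na(PE)
  emit(IUZ[m], PE[m], rep(Az, nz + 1L)[m])
  m <- Fz & !is.na(PW)
  emit(IUZ[m], PW[m], -rep(Az, nz + 1L)[m])
  # Dirichlet uz rows
  d <- bc$uzD
  emit(IUZ[d], IUZ[d], rep(1, sum(d)))
  b[IUZ[d]] <- bc$uzV[d]

  ## ---------------- radial momentum (ur) ----------------
  Fr <- !bc$urD
  Azr <- 2 * pi * rc * dz                 # radial-flux areas at cell centres
  Mrow <- mu * (Azr / dr)                 # nr x nz, recycled per row
  aN <- rbind(Mrow, 0)                    # link to ur[ii+1], ii <= nr
  aS <- rbind(0, Mrow)                    # link to ur[ii-1], ii >= 2
  drpv <- c(NA, rc[-1] - rc[-nr], NA)     # ur CV radial extent, ii = 2..nr
  mu_f <- (mu[-nr, , drop = FALSE] + mu[-1, , drop = FALSE]) / 2  # rows = ii-1
  Afz <- 2 * pi * rf[2:nr] * drpv[2:nr]   # z-face areas of ur CVs, ii = 2..nr
  # hoop term -mu u_r / r^2 integrated over the CV (positive diagonal)
  hoop <- rbind(0, mu_f * matrix(2 * pi * drpv[2:nr] * dz / rf[2:nr], nr - 1L, nz), 0)
  muz <- (mu_f[, -nz, drop = FALSE] + mu_f[, -1, drop = FALSE]) / 2  # (nr-1) x (nz-1)
  aEz <- rbind(0, cbind(muz * matrix(Afz / dz, nr - 1L, nz - 1L), 0), 0)
  aWz <- rbind(0, cbind(0, muz * matrix(Afz / dz, nr - 1L, nz - 1L)), 0)
  # inlet ghost for U > 0: ur = 0 on the inlet plane, half-cell link
  inlet_diag <- matrix(0, nr + 1L, nz)
  if (U > 0)
    inlet_diag[2:nr, 1] <- mu_f[, 1] * Afz / (dz / 2)
  # convection
  uzbar <- (uz0[-nr, , drop = FALSE] + uz0[-1, , drop = FALSE]) / 2  # rows = ii-1
  Fzco <- rho * matrix(Afz, nr - 1L, nz + 1L) * uzbar
  FwU <- rbind(0, Fzco[, -(nz + 1L), drop = FALSE], 0)
  FeU <- rbind(0, Fzco[, -1, drop = FALSE], 0)
  Frcell <- rho * matrix(Azr, nr, nz) * (ur0[-(nr + 1L), , drop = FALSE] + ur0[-1, , drop = FALSE]) / 2
  FsU <- rbind(0, Frcell[-nr, , drop = FALSE], 0)
  FnU <- rbind(0, Frcell[-1, , drop = FALSE], 0)
  aWc <- pmax(FwU, 0); aEc <- pmax(-FeU, 0)
  aSc <- pmax(FsU, 0); aNc <- pmax(-FnU, 0)
  netF <- (FeU - FwU) + (FnU - FsU)
  aW <- aWz + aWc; aE <- aEz + aEc
  aS <- aS + aSc; aN <- aN + aNc
  aP <- aW + aE + aN + aS + netF + hoop + inlet_diag

  emit(IUR[Fr], IUR[Fr], aP[Fr])
  W_idx <- cbind(NA, IUR[, -nz, drop = FALSE])
  E_idx <- cbind(IUR[, -1, drop = FALSE], NA)
  N_idx <- rbind(IUR[-1, , drop = FALSE], NA)
  S_idx <- rbind(NA, IUR[-(nr + 1L), , drop = FALSE])
  for (dir in list(list(W_idx, aW), list(E_idx, aE), list(N_idx, aN), list(S_idx, aS))) {
    m <- Fr & !is.na(dir[[1]]) & dir[[2]] != 0
    emit(IUR[m], dir[[1]][m], -dir[[2]][m])
  }
  PS <- rbind(NA, IP); PN <- rbind(IP, NA)   # p below / above the ur face
  Arf_m <- matrix(Arf, nr + 1L, nz)
  m <- Fr & !is.na(PS)
  emit(IUR[m], PS[m], -Arf_m[m])
  m <- Fr & !is.na(PN)
  emit(IUR[m], PN[m], Arf_m[m])
  d <- bc$urD
  emit(IUR[d], IUR[d], rep(1, sum(d)))

  ## ---------------- continuity / pressure ----------------
  fluid <- !solid
  emit(IP[fluid], IUZ[, -1, drop = FALSE][fluid], Az_m[fluid])
  emit(IP[fluid], IUZ[, -(nz + 1L), drop = FALSE][fluid], -Az_m[fluid])
  emit(IP[fluid], IUR[-1, , drop = FALSE][fluid], matrix(Arf[-1], nr, nz)[fluid])
  emit(IP[fluid], IUR[-(nr + 1L), , drop = FALSE][fluid], -matrix(Arf[-(nr + 1L)], nr, nz)[fluid])
  if (any(solid)) emit(IP[solid], IP[solid], rep(1, sum(solid)))

  A <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
                            x = unlist(tx[seq_len(nt)]), dims = c(N, N))
  s <- 1 / Matrix::rowSums(abs(A))
  x <- as.numeric(Matrix::solve(Matrix::Diagonal(x = s) %*% A, s * b))
  list(uz = matrix(x[seq_len(nuz)], nr, nz + 1L),
       ur = matrix(x[nuz + seq_len(nur)], nr + 1L, nz),
       p = matrix(x[nuz + nur + seq_len(np)], nr, nz))
}

# Cell-centred shear-rate magnitude sqrt(2 D:D) in axisymmetric
# coordinates; solid-adjacent radial gradients use the half-cell distance
# to the material interface.
shear_rate_core <- function(uz, ur, mesh, solid) {
  nr <- mesh$nr; nz <- mesh$nz
  dz <- mesh$dz; dr <- mesh$dr; rc <- mesh$r_c; rf <- mesh$r_faces
  uzc <- (uz[, -(nz + 1L), drop = FALSE] + uz[, -1, drop = FALSE]) / 2
  urc <- (ur[-(nr + 1L), , drop = FALSE] + ur[-1, , drop = FALSE]) / 2
  ezz <- (uz[, -1, drop = FALSE] - uz[, -(nz + 1L), drop = FALSE]) / dz
  err <- (ur[-1, , drop = FALSE] - ur[-(nr + 1L), , drop = FALSE]) / dr
  ett <- urc / rc
  # d(uz)/dr on radial faces, then averaged to centres
  if (nr > 1L) {
    den <- matrix(rc[-1] - rc[-nr], nr - 1L, nz)
    up_solid <- solid[-1, , drop = FALSE] & !solid[-nr, , drop = FALSE]
    lo_solid <- solid[-nr, , drop = FALSE] & !solid[-1, , drop = FALSE]
    den[up_solid] <- (matrix(rf[2:nr], nr - 1L, nz) - matrix(rc[-nr], nr - 1L, nz))[up_solid]
    den[lo_solid] <- (matrix(rc[-1], nr - 1L, nz) - matrix(rf[2:nr], nr - 1L, nz))[lo_solid]
    g <- (uzc[-1, , drop = FALSE] - uzc[-nr, , drop = FALSE]) / den
    duzdr <- rbind(g[1, , drop = FALSE],
                   (g[-(nr - 1L), , drop = FALSE] + g[-1, , drop = FALSE]) / 2,
                   g[nr - 1L, , drop = FALSE])
    if (nr == 2L) duzdr <- rbind(g, g)
  } else duzdr <- matrix(0, nr, nz)
  if (nz > 1L) {
    gz <- (urc[, -1, drop = FALSE] - urc[, -nz, drop = FALSE]) / dz
    durdz <- cbind(gz[, 1, drop = FALSE],
                   (gz[, -(nz - 1L), drop = FALSE] + gz[, -1, drop = FALSE]) / 2,
                   gz[, nz - 1L, drop = FALSE])
    if (nz == 2L) durdz <- cbind(gz, gz)
  } else durdz <- matrix(0, nr, nz)
  sqrt(2 * (err^2 + ezz^2 + ett^2) + (duzdr + durdz)^2)
}

#' Shear-rate magnitude of a flow field
#'
#' \eqn{\dot\gamma = \sqrt{2\,D:D}} from the symmetric strain-rate tensor
#' in axisymmetric coordinates, evaluated at cell centres.
#'
#' @param flow a `flow_field` from [solve_flow()].
#' @param mesh the mesh the field lives on.
#' @return `nr x nz` matrix of shear rates (1/s).
#' @export
shear_rate <- function(flow, mesh) {
  shear_rate_core(flow$uz, flow$ur, mesh, flow$solid)
}

#' Solve the quasi-steady laminar flow field
#'
#' Incompressible momentum + continuity on a staggered axisymmetric grid:
#' uniform axial inflow (or a closed free-slip inlet when `U = 0`),
#' traction-free outflow, no-slip on the vessel wall, and the electrode as
#' a blocked-cell moving boundary whose surface carries the pullback
#' velocity `-V` in z.  The shear-thinning viscosity closes through Picard
#' iteration with upwind-biased convection and under-relaxation; the
#' coupled linear system is solved directly, so the discrete divergence of
#' the converged field is at rounding level.
#'
#' @param mesh a [build_mesh()] mesh.
#' @param props a [material_properties()].
#' @param cy a [carreau_yasuda()] parameter set (set `mu_0` close to
#'   `mu_inf` for a Newtonian limit).
#' @param U uniform inlet velocity (m/s).
#' @param electrode an [electrode_state()], or `NULL` for no electrode.
#' @param settings a [solver_settings()].
#' @param init optional previous `flow_field` used as warm start.
#' @return an object of class `flow_field`: staggered velocities `uz`
#'   (`nr x (nz+1)`), `ur` (`(nr+1) x nz`), pressure `p`, cell shear rate
#'   `gamma_dot`, effective viscosity `mu_eff`, iteration diagnostics and
#'   the relative divergence `div_rel`.
#' @export
solve_flow <- function(mesh, props, cy, U = 0, electrode = NULL,
                       settings = solver_settings(), init = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"), U >= 0)
  nr <- mesh$nr; nz <- mesh$nz
  solid <- mesh$region == REGION_WALL
  emask <- matrix(FALSE, nr, nz)
  V <- 0
  if (!is.null(electrode)) {
    emask <- electrode_mask_at(mesh, electrode)
    V <- electrode$pullback_velocity
    solid <- solid | emask
  }
  bc <- flow_bc(mesh, solid, emask, U, V)
  if (!is.null(init)) {
    uz <- init$uz; ur <- init$ur
  } else {
    uz <- matrix(0, nr, nz + 1L); ur <- matrix(0, nr + 1L, nz)
  }
  uz[bc$uzD] <- bc$uzV[bc$uzD]
  ur[bc$urD] <- 0
  rho <- props$rho_b
  tol <- settings$linear_tolerance
  res_hist <- numeric(0)
  sol <- NULL
  # Picard iteration with Aitken dynamic relaxation: the fixed-point
  # residual r_k = G(u_k) - u_k drives an adaptive relaxation factor,
  # starting from the configured under-relaxation.
  w <- settings$relax
  r_prev <- NULL
  for (k in seq_len(settings$picard_max_iter)) {
    gam <- shear_rate_core(uz, ur, mesh, solid)
    mu <- carreau_yasuda_viscosity(gam, cy)
    sol <- flow_solve_once(mesh, bc, solid, mu, rho, uz, ur, U, V)
    r_k <- c(sol$uz - uz, sol$ur - ur)
    scale <- max(U, V, max(abs(sol$uz)), max(abs(sol$ur)), 1e-12)
    res <- max(abs(r_k)) / scale
    res_hist <- c(res_hist, res)
    if (res < tol) { uz <- sol$uz; ur <- sol$ur; break }
    if (!is.null(r_prev)) {
      dr <- r_k - r_prev
      den <- sum(dr * dr)
      if (den > 0) w <- max(0.1, min(2, -w * sum(r_prev * dr) / den))
    }
    uz <- uz + w * (sol$uz - uz)
    ur <- ur + w * (sol$ur - ur)
    r_prev <- r_k
  }
  if (res_hist[length(res_hist)] >= tol)
    stop("flow solve did not converge in ", settings$picard_max_iter,
         " Picard iterations; residual history: ",
         paste(signif(res_hist, 3), collapse = ", "))
  gam <- shear_rate_core(uz, ur, mesh, solid)
  mu <- carreau_yasuda_viscosity(gam, cy)
  div <- flow_divergence(uz, ur, mesh)
  R_lumen <- mesh$r_faces[mesh$i_lumen + 1L]
  r_elec <- if (!is.null(mesh$geom)) mesh$geom$electrode_radius else 0
  Qscale <- max(pi * R_lumen^2 * U, pi * r_elec^2 * V, 1e-30)
  fluid <- !solid
  structure(list(uz = uz, ur = ur, p = sol$p, gamma_dot = gam, mu_eff = mu,
                 U = U, V = V, solid = solid, emask = emask,
                 iterations = length(res_hist), residuals = res_hist,
                 div_rel = max(abs(div[fluid])) / Qscale),
            class = "flow_field")
}

# Discrete divergence (net volume flux, m^3/s) of a staggered field.
flow_divergence <- function(uz, ur, mesh) {
  nr <- mesh$nr; nz <- mesh$nz
  Arf <- 2 * pi * mesh$r_faces * mesh$dz
  matrix(mesh$Az, nr, nz) * (uz[, -1, drop = FALSE] - uz[, -(nz + 1L), drop = FALSE]) +
    matrix(Arf[-1], nr, nz) * ur[-1, , drop = FALSE] -
    matrix(Arf[-(nr + 1L)], nr, nz) * ur[-(nr + 1L), , drop = FALSE]
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field U = %g mm/s, V = %g mm/s, %d Picard iterations, rel. divergence %.2e>\n",
              x$U * 1e3, x$V * 1e3, x$iterations, x$div_rel))
  invisible(x)
}
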