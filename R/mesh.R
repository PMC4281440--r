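#' Build the structured axisymmetric mesh
#'
#' Cells are arranged on an (r, z) grid with the axis at r = 0, the inlet
#' at z = 0 and uniform axial spacing.  Radial faces are pinned exactly to
#' the electrode radius and to the lumen--wall interface so that material
#' boundaries are conforming; spacing is uniform within each radial band.
#' Cell volumes are the axisymmetric volumes \eqn{2\pi \bar r \Delta r
#' \Delta z}.
#'
#' @param geom a [vein_geometry()].
#' @param nr total number of radial cells (split between the inner core
#'   under the electrode radius, the outer lumen and the wall).
#' @param nz number of axial cells.
#' @return an object of class `axisym_mesh` with face coordinates, cell
#'   centres, per-cell region labels (`1` lumen, `2` wall), cell volumes
#'   and face areas.
#' @examples
#' m <- build_mesh(vein_geometry(), nr = 38, nz = 240)
#' m$nr * m$nz  # 9120 cells
#' @export
build_mesh <- function(geom, nr = 38L, nz = 240L) {
  stopifnot(inherits(geom, "vein_geometry"))
  nr <- as.integer(nr); nz <- as.integer(nz)
  if (nr < 8L || nz < 4L)
    stop("mesh too coarse: need nr >= 8 and nz >= 4")
  R <- geom$lumen_radius; tw <- geom$wall_thickness; re <- geom$electrode_radius
  Rout <- R + tw
  h <- Rout / nr
  n_i <- max(2L, as.integer(round(re / h)))
  n_w <- max(2L, as.integer(round(tw / h)))
  n_l <- nr - n_i - n_w
  if (n_l < 4L)
    stop("mesh too coarse: cannot separate electrode core, lumen and wall ",
         "with nr = ", nr, " radial cells")
  r_faces <- c(seq(0, re, length.out = n_i + 1L),
               seq(re, R, length.out = n_l + 1L)[-1L],
               seq(R, Rout, length.out = n_w + 1L)[-1L])
  z_faces <- seq(0, geom$domain_length, length.out = nz + 1L)
  region <- c(rep(REGION_LUMEN, n_i + n_l), rep(REGION_WALL, n_w))
  new_axisym_mesh(r_faces, z_faces, region, geom,
                  i_core = n_i, i_lumen = n_i + n_l)
}

# Low-level constructor: arbitrary radial faces and per-ring region labels.
# Used by build_mesh() and by the verification fixtures (slab/annulus
# meshes that do not correspond to the vein geometry).
new_axisym_mesh <- function(r_faces, z_faces, region_ring, geom = NULL,
                            i_core = 0L, i_lumen = length(region_ring)) {
  nr <- length(r_faces) - 1L
  nz <- length(z_faces) - 1L
  if (any(diff(r_faces) <= 0) || any(diff(z_faces) <= 0))
    stop("face coordinates must be strictly increasing")
  dz <- diff(z_faces)
  if (max(abs(dz - dz[1])) > 1e-12 * dz[1])
    stop("axial spacing must be uniform")
  dz <- dz[1]
  dr <- diff(r_faces)
  r_c <- (r_faces[-1L] + r_faces[-(nr + 1L)]) / 2
  z_c <- (z_faces[-1L] + z_faces[-(nz + 1L)]) / 2
  Az <- pi * (r_faces[-1L]^2 - r_faces[-(nr + 1L)]^2)  # z-face area per ring
  Ar <- 2 * pi * r_faces * dz                          # r-face area per face
  vol <- outer(Az * dz, rep(1, nz))
  region <- matrix(rep(as.integer(region_ring), nz), nr, nz)
  structure(list(r_faces = r_faces, z_faces = z_faces, r_c = r_c, z_c = z_c,
                 dr = dr, dz = dz, nr = nr, nz = nz, region = region,
                 region_ring = as.integer(region_ring), vol = vol,
                 Az = Az, Ar = Ar, geom = geom,
                 i_core = as.integer(i_core), i_lumen = as.integer(i_lumen)),
            class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf("<axisym_mesh %d x %d cells, r in [0, %.3g] mm, z in [0, %.3g] mm>\n",
              x$nr, x$nz, max(x$r_faces) * 1e3, max(x$z_faces) * 1e3))
  invisible(x)
}

#' Electrode state during pullback
#'
#' Tracks the axial position of the electrode end nearer the inlet
#' (`z_proximal`), the constant pullback velocity (motion directed toward
#' the inlet, against the +z blood flow direction) and the isothermal
#' surface temperature.
#'
#' @param z_proximal proximal-end axial position (m).
#' @param pullback_velocity pullback speed V (m/s), `>= 0`.
#' @param surface_temperature electrode surface temperature (K).
#' @return an object of class `electrode_state`.
#' @export
electrode_state <- function(z_proximal = 20e-3, pullback_velocity = 1e-3,
                            surface_temperature = 358) {
  if (pullback_velocity < 0) stop("field 'pullback_velocity': must be >= 0")
  structure(list(z_proximal = z_proximal,
                 pullback_velocity = pullback_velocity,
                 surface_temperature = surface_temperature),
            class = "electrode_state")
}

#' Advance the electrode by one time increment
#'
#' The proximal end moves toward the inlet: `z_proximal` decreases by
#' `V * dt`.
#'
#' @param state an [electrode_state()].
#' @param dt time increment (s), `> 0`.
#' @return updated [electrode_state()].
#' @export
advance_electrode <- function(state, dt) {
  stopifnot(inherits(state, "electrode_state"), dt > 0)
  state$z_proximal <- state$z_proximal - state$pullback_velocity * dt
  state
}

#' Per-cell electrode occupancy mask
#'
#' A cell is occupied by the electrode when its centre lies at
#' `r <= electrode_radius` and within the half-open axial interval
#' `[z_proximal, z_proximal + L)`.  The electrode must lie entirely inside
#' the domain; if pullback has carried it (partially) outside, a classed
#' condition `rfavein_electrode_exit` is signalled so that a transient run
#' can be truncated.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param state an [electrode_state()].
#' @param electrode_length electrode length L (m); defaults to the value in
#'   the mesh geometry.
#' @return logical `nr x nz` matrix.
#' @export
electrode_mask_at <- function(mesh, state, electrode_length = NULL) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(state, "electrode_state"))
  L <- electrode_length %||% mesh$geom$electrode_length
  re <- mesh$geom$electrode_radius
  zp <- state$z_proximal
  eps <- 1e-12
  if (zp < -eps || zp + L > max(mesh$z_faces) + eps) {
    cond <- structure(class = c("rfavein_electrode_exit", "error", "condition"),
                      list(message = sprintf(
                        "electrode outside domain: z_proximal = %.4g mm", zp * 1e3),
                        call = sys.call()))
    stop(cond)
  }
  in_r <- mesh$r_c < re - eps
  in_z <- mesh$z_c >= zp - eps & mesh$z_c < zp + L - eps
  outer(in_r, in_z, `&`)
}
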