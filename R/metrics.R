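#' Temperature profile along the lumen--wall interface
#'
#' Interpolates the cell-centred temperature to the conforming interface
#' face at r = R at every axial station.  The interpolation is linear
#' within each material and flux-consistent across the face (the same
#' harmonic-mean construction the diffusion operator uses), so the
#' returned values are the discrete interface temperatures.
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh.
#' @param props a [material_properties()] supplying the two conductivities.
#' @return an object of class `interface_profile`: `z` (m, strictly
#'   increasing), `T` (K) and `time` (s).
#' @export
extract_interface_profile <- function(Tf, mesh, props = material_properties()) {
  iR <- mesh$i_lumen
  stopifnot(iR >= 1L)
  if (iR == mesh$nr) {  # no wall band: sample the outermost ring
    Tface <- Tf$T[iR, ]
  } else {
    rf <- mesh$r_faces[iR + 1L]
    d1 <- rf - mesh$r_c[iR]; d2 <- mesh$r_c[iR + 1L] - rf
    rp <- ring_props(mesh, props)
    wl <- rp$k[iR] / d1; ww <- rp$k[iR + 1L] / d2
    Tface <- (wl * Tf$T[iR, ] + ww * Tf$T[iR + 1L, ]) / (wl + ww)
  }
  structure(list(z = mesh$z_c, T = Tface, time = Tf$time),
            class = "interface_profile")
}

#' Peak of an interface temperature profile
#'
#' @param profile an `interface_profile` (or any list with `z` and `T`).
#' @return list with `T_peak` (K) and `z_peak` (m); ties broken by the
#'   smallest z.
#' @export
peak_interface_temperature <- function(profile) {
  if (!length(profile$T)) stop("empty interface profile")
  k <- which.max(profile$T)   # which.max returns the first (smallest z) tie
  list(T_peak = profile$T[k], z_peak = profile$z[k])
}

#' Thermally influenced volume fraction
#'
#' Fraction of the whole geometry (lumen + wall) with temperature above a
#' threshold, weighted by the axisymmetric cell volumes (or by
#' symmetry-plane cell areas with `weight = "area"`).
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh.
#' @param threshold_K threshold temperature (K); the default, body
#'   temperature + 1 K, defines "influenced" as a 1 K rise.
#' @param weight `"volume"` (default) or `"area"`.
#' @return fraction in `[0, 1]`.
#' @export
influenced_fraction <- function(Tf, mesh, threshold_K = 310.15,
                                weight = c("volume", "area")) {
  weight <- match.arg(weight)
  w <- if (weight == "volume") mesh$vol else outer(mesh$dr, rep(mesh$dz, mesh$nz))
  sum(w[Tf$T > threshold_K]) / sum(w)
}

#' Influenced-fraction threshold sweep
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh.
#' @param thresholds vector of thresholds (K).
#' @param weight passed to [influenced_fraction()].
#' @return data.frame with columns `threshold_K` and `fraction`
#'   (non-increasing in the threshold).
#' @export
influenced_sweep <- function(Tf, mesh,
                             thresholds = seq(309.65, 313.15, by = 0.25),
                             weight = "volume") {
  data.frame(threshold_K = thresholds,
             fraction = vapply(thresholds, function(th)
               influenced_fraction(Tf, mesh, th, weight), numeric(1)))
}

#' Thermal energy absorbed by the vein wall
#'
#' \eqn{\sum_{wall} \rho_w C_{pw} (T - T_{body}) V_{cell}} over the wall
#' cells.
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh.
#' @param props a [material_properties()].
#' @param body_T reference (body) temperature (K).
#' @return energy (J).
#' @export
wall_absorbed_energy <- function(Tf, mesh, props, body_T = 309.15) {
  w <- mesh$region == REGION_WALL
  sum(props$rho_w * props$c_pw * (Tf$T[w] - body_T) * mesh$vol[w])
}

#' Scenario metrics report
#'
#' Collects the summary quantities for one temperature snapshot: peak
#' interfacial temperature and its axial location, influenced volume
#' fraction (threshold body + 1 K by default), tissue-damage volume
#' fractions above 40 C (damage onset) and 50 C (irreversible damage),
#' and the wall absorbed energy.
#'
#' @param Tf a [temperature_field()].
#' @param mesh the mesh.
#' @param cfg the [scenario_config()].
#' @param influence_threshold threshold (K) for the influenced fraction.
#' @param damage_threshold,irreversible_threshold fixed damage thresholds
#'   (K); defaults 313.15 K (40 C) and 323.15 K (50 C), reported as
#'   instantaneous-exceedance fractions.
#' @return an object of class `metrics_report`.
#' @export
metrics_report <- function(Tf, mesh, cfg,
                           influence_threshold = cfg$body_temperature + 1,
                           damage_threshold = 313.15,
                           irreversible_threshold = 323.15) {
  prof <- extract_interface_profile(Tf, mesh, cfg$properties)
  pk <- peak_interface_temperature(prof)
  structure(list(
    scenario = cfg$id, time = Tf$time,
    peak_interface_T = pk$T_peak, peak_interface_z = pk$z_peak,
    max_domain_T = max(Tf$T),
    influenced_fraction = influenced_fraction(Tf, mesh, influence_threshold),
    influenced_fraction_area = influenced_fraction(Tf, mesh, influence_threshold, "area"),
    damage_fraction_313K = influenced_fraction(Tf, mesh, damage_threshold),
    irreversible_fraction_323K = influenced_fraction(Tf, mesh, irreversible_threshold),
    wall_energy_J = wall_absorbed_energy(Tf, mesh, cfg$properties,
                                         cfg$body_temperature)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics '%s' t = %.3g s: peak interface %.2f K at z = %.1f mm, influenced %.1f%%, wall %.3g J>\n",
              x$scenario, x$time, x$peak_interface_T, x$peak_interface_z * 1e3,
              100 * x$influenced_fraction, x$wall_energy_J))
  invisible(x)
}
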