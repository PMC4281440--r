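#' Thermophysical material properties of blood and vein wall
#'
#' Defaults are the constant properties used throughout the model: blood
#' density 1050 kg/m^3, reference dynamic viscosity 0.0035 kg/(m s), wall
#' density 1120 kg/m^3, specific heats 3820 / 3780 J/(kg K) and thermal
#' conductivities 0.492 / 0.56 W/(m K) for blood and wall respectively.
#' Properties are temperature-independent; the wall is a single homogeneous
#' isotropic layer.
#'
#' @param rho_b blood density (kg/m^3).
#' @param mu_b blood reference dynamic viscosity (kg/(m s)); used for the
#'   Reynolds number, not for the momentum equation (see
#'   [carreau_yasuda()]).
#' @param rho_w vein-wall density (kg/m^3).
#' @param c_pb blood specific heat (J/(kg K)).
#' @param c_pw vein-wall specific heat (J/(kg K)).
#' @param k_b blood thermal conductivity (W/(m K)).
#' @param k_w vein-wall thermal conductivity (W/(m K)).
#' @return an object of class `material_properties`.
#' @export
material_properties <- function(rho_b = 1050, mu_b = 0.0035, rho_w = 1120,
                                c_pb = 3820, c_pw = 3780,
                                k_b = 0.492, k_w = 0.56) {
  out <- list(rho_b = rho_b, mu_b = mu_b, rho_w = rho_w,
              c_pb = c_pb, c_pw = c_pw, k_b = k_b, k_w = k_w)
  for (f in names(out)) {
    v <- out[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("field '", f, "': must be a single strictly positive number")
  }
  structure(out, class = "material_properties")
}

#' Carreau-Yasuda shear-thinning viscosity parameters
#'
#' Blood is modelled as a generalized Newtonian fluid with viscosity
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a},}
#' interpolating between the zero-shear viscosity \eqn{\mu_0} and the
#' infinite-shear viscosity \eqn{\mu_\infty}.
#'
#' @param mu_inf infinite-shear viscosity (kg/(m s)).
#' @param mu_0 zero-shear viscosity (kg/(m s)); must exceed `mu_inf`.
#' @param n power index (dimensionless).
#' @param a Yasuda exponent (dimensionless).
#' @param lambda relaxation time (s).
#' @return an object of class `carreau_yasuda`.
#' @export
carreau_yasuda <- function(mu_inf = 0.0035, mu_0 = 0.16, n = 0.2128,
                           a = 0.64, lambda = 8.2) {
  if (!(mu_inf > 0)) stop("field 'mu_inf': must be > 0")
  if (!(mu_0 > mu_inf)) stop("field 'mu_0': must exceed mu_inf")
  if (!(lambda > 0)) stop("field 'lambda': must be > 0")
  if (!(a > 0)) stop("field 'a': must be > 0")
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, n = n, a = a, lambda = lambda),
            class = "carreau_yasuda")
}

#' Vessel and electrode geometry
#'
#' Defaults describe a 3 mm-diameter, 60 mm-long lumen with a 0.4 mm
#' homogeneous wall, and a 0.4 mm-diameter, 10 mm-long coaxial electrode
#' whose proximal (inlet-side) end starts 20 mm from the inlet plane.
#' Arguments accept SI numbers or unit strings (see [parse_quantity()]).
#'
#' @param lumen_radius lumen radius R (m).
#' @param wall_thickness vein-wall thickness (m).
#' @param domain_length axial extent of the model, inlet to outlet (m).
#' @param electrode_radius electrode radius (m); must be `< lumen_radius`.
#' @param electrode_length electrode length L (m).
#' @param electrode_start_z axial position of the electrode end nearer the
#'   inlet at t = 0 (m).
#' @return an object of class `vein_geometry`.
#' @export
vein_geometry <- function(lumen_radius = 1.5e-3, wall_thickness = 0.4e-3,
                          domain_length = 60e-3, electrode_radius = 0.2e-3,
                          electrode_length = 10e-3, electrode_start_z = 20e-3) {
  g <- list(lumen_radius = parse_quantity(lumen_radius, "length", "lumen_radius"),
            wall_thickness = parse_quantity(wall_thickness, "length", "wall_thickness"),
            domain_length = parse_quantity(domain_length, "length", "domain_length"),
            electrode_radius = parse_quantity(electrode_radius, "length", "electrode_radius"),
            electrode_length = parse_quantity(electrode_length, "length", "electrode_length"),
            electrode_start_z = parse_quantity(electrode_start_z, "length", "electrode_start_z"))
  for (f in setdiff(names(g), "electrode_start_z"))
    if (g[[f]] <= 0) stop("field '", f, "': must be strictly positive")
  if (g$electrode_start_z < 0)
    stop("field 'electrode_start_z': must be non-negative")
  if (g$electrode_radius >= g$lumen_radius)
    stop("field 'electrode_radius': must be smaller than lumen_radius")
  if (g$electrode_start_z + g$electrode_length > g$domain_length + 1e-12)
    stop("field 'electrode_start_z': electrode must fit inside the domain")
  structure(g, class = "vein_geometry")
}

#' Numerical solver settings
#'
#' @param nr number of radial cells (faces are pinned to the electrode
#'   radius and to the lumen--wall interface; see [build_mesh()]).
#' @param nz number of axial cells.
#' @param dt_max maximum time step (s).
#' @param cfl_limit advective CFL target in (0, 1].
#' @param flow_update_rows re-solve the quasi-steady flow whenever the
#'   electrode mask has shifted by at least this many axial cell rows.
#' @param linear_tolerance relative convergence tolerance of the nonlinear
#'   (Picard) flow iteration, measured against the inlet/pullback velocity
#'   scale.
#' @param picard_max_iter maximum Picard iterations for the flow solve.
#' @param relax Picard under-relaxation factor applied while the residual
#'   is large; full steps are taken once the iteration is nearly converged.
#' @param q_rf_volumetric volumetric RF deposition (W/m^3).  The electrode
#'   surface is an isothermal Dirichlet boundary, so heat enters through it
#'   alone and this term defaults to 0; it is retained for completeness.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(nr = 38L, nz = 240L, dt_max = 5e-3,
                            cfl_limit = 0.5, flow_update_rows = 1L,
                            linear_tolerance = 1e-8, picard_max_iter = 60L,
                            relax = 0.7, q_rf_volumetric = 0) {
  if (!(dt_max > 0)) stop("field 'dt_max': must be > 0")
  if (!(cfl_limit > 0 && cfl_limit <= 1))
    stop("field 'cfl_limit': must lie in (0, 1]")
  if (nr < 4 || nz < 4) stop("field 'nr'/'nz': need at least 4 cells per direction")
  if (flow_update_rows < 1) stop("field 'flow_update_rows': must be >= 1")
  structure(list(nr = as.integer(nr), nz = as.integer(nz), dt_max = dt_max,
                 cfl_limit = cfl_limit,
                 flow_update_rows = as.integer(flow_update_rows),
                 linear_tolerance = linear_tolerance,
                 picard_max_iter = as.integer(picard_max_iter),
                 relax = relax, q_rf_volumetric = q_rf_volumetric),
            class = "solver_settings")
}

#' Define a treatment scenario
#'
#' A scenario couples one inlet blood velocity U with one electrode
#' pullback velocity V (withdrawal directed toward the inlet, against the
#' flow), the electrode surface temperature, the body (inlet/initial)
#' temperature and the treatment duration.  Velocity and temperature
#' arguments accept unit strings (`"5 mm/s"`, `"85 C"`).
#'
#' @param inlet_velocity uniform inlet blood velocity U (m/s), `>= 0`.
#' @param pullback_velocity electrode pullback speed V (m/s), `>= 0`;
#'   positive V moves the electrode toward the inlet.
#' @param electrode_temperature electrode surface temperature (K);
#'   default 358 K (85 C).
#' @param body_temperature body/inlet/initial temperature (K); default
#'   309.15 K (36 C).
#' @param duration treatment time (s).
#' @param snapshot_times times at which temperature snapshots are stored;
#'   default every second from 0.5 s plus the final time.
#' @param geometry a [vein_geometry()].
#' @param properties a [material_properties()].
#' @param rheology a [carreau_yasuda()].
#' @param numerics a [solver_settings()].
#' @param id optional scenario identifier (derived from U and V if absent).
#' @return an object of class `scenario_config` (already validated).
#' @examples
#' cfg <- scenario_config(inlet_velocity = "5 mm/s", pullback_velocity = "1 mm/s")
#' cfg$inlet_velocity  # 0.005
#' @export
scenario_config <- function(inlet_velocity = 0, pullback_velocity = 0,
                            electrode_temperature = 358,
                            body_temperature = 309.15,
                            duration = 7, snapshot_times = NULL,
                            geometry = vein_geometry(),
                            properties = material_properties(),
                            rheology = carreau_yasuda(),
                            numerics = solver_settings(), id = NULL) {
  U <- parse_quantity(inlet_velocity, "velocity", "inlet_velocity")
  V <- parse_quantity(pullback_velocity, "velocity", "pullback_velocity")
  Te <- parse_quantity(electrode_temperature, "temperature", "electrode_temperature")
  Tb <- parse_quantity(body_temperature, "temperature", "body_temperature")
  dur <- parse_quantity(duration, "time", "duration")
  if (is.null(snapshot_times)) {
    snapshot_times <- seq(0.5, dur, by = 1)
    snapshot_times <- unique(c(snapshot_times[snapshot_times <= dur], dur))
  } else {
    snapshot_times <- sort(unique(vapply(snapshot_times, parse_quantity,
                                         numeric(1), kind = "time",
                                         field = "snapshot_times")))
  }
  if (is.null(id)) id <- sprintf("U%g_V%g", U * 1e3, V * 1e3)
  cfg <- structure(list(inlet_velocity = U, pullback_velocity = V,
                        electrode_temperature = Te, body_temperature = Tb,
                        duration = dur, snapshot_times = snapshot_times,
                        geometry = geometry, properties = properties,
                        rheology = rheology, numerics = numerics, id = id),
                   class = "scenario_config")
  validate_config(cfg)
}

#' Validate a scenario configuration
#'
#' Checks every invariant of the configuration (positivity of material
#' properties, geometric consistency, electrode hotter than the body,
#' snapshot times inside the treatment window) and returns the
#' configuration unchanged on success.
#'
#' @param cfg a [scenario_config()].
#' @return `cfg`, invisibly unchanged, or an error naming the offending
#'   field.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) stop("not a scenario_config")
  if (!inherits(cfg$geometry, "vein_geometry")) cfg$geometry <- do.call(vein_geometry, unclass(cfg$geometry))
  if (!inherits(cfg$properties, "material_properties")) cfg$properties <- do.call(material_properties, unclass(cfg$properties))
  if (!inherits(cfg$rheology, "carreau_yasuda")) cfg$rheology <- do.call(carreau_yasuda, unclass(cfg$rheology))
  if (!inherits(cfg$numerics, "solver_settings")) cfg$numerics <- do.call(solver_settings, unclass(cfg$numerics))
  if (cfg$inlet_velocity < 0) stop("field 'inlet_velocity': must be >= 0")
  if (cfg$pullback_velocity < 0) stop("field 'pullback_velocity': must be >= 0")
  if (!(cfg$duration >= 0)) stop("field 'duration': must be >= 0")
  if (!(cfg$electrode_temperature > cfg$body_temperature))
    stop("field 'electrode_temperature': must exceed body_temperature ",
         "(no heating possible otherwise)")
  if (length(cfg$snapshot_times) &&
      (min(cfg$snapshot_times) < 0 || max(cfg$snapshot_times) > cfg$duration + 1e-12))
    stop("field 'snapshot_times': must lie within [0, duration]")
  cfg
}

#' Reynolds number of the lumen flow
#'
#' \eqn{Re = \rho U D / \mu}: ratio of inertial to viscous forces.  Values
#' below 2300 indicate laminar pipe flow.
#'
#' @param U velocity (m/s). @param D diameter (m).
#' @param rho density (kg/m^3). @param mu dynamic viscosity (kg/(m s)).
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(0.023, 0.003, 1050, 0.0035)  # 20.7
#' @export
reynolds_number <- function(U, D, rho, mu) {
  if (any(mu <= 0)) stop("field 'mu': viscosity must be > 0")
  if (any(U < 0) || any(D < 0) || any(rho < 0))
    stop("U, D and rho must be non-negative")
  rho * U * D / mu
}

#' Is the scenario inside the laminar regime?
#'
#' Computes the Reynolds number at the inlet velocity using the lumen
#' diameter and the reference blood viscosity, and compares against the
#' laminar threshold 2300.
#'
#' @param cfg a [scenario_config()].
#' @return `TRUE` iff `Re < 2300`.
#' @export
assert_laminar <- function(cfg) {
  cfg <- validate_config(cfg)
  Re <- reynolds_number(cfg$inlet_velocity, 2 * cfg$geometry$lumen_radius,
                        cfg$properties$rho_b, cfg$properties$mu_b)
  Re < 2300
}

# ---- configuration file I/O --------------------------------------------

cfg_to_list <- function(cfg) {
  num <- function(x) format_si(x)
  list(
    id = cfg$id,
    inlet_velocity = paste(num(cfg$inlet_velocity), "m/s"),
    pullback_velocity = paste(num(cfg$pullback_velocity), "m/s"),
    electrode_temperature = paste(num(cfg$electrode_temperature), "K"),
    body_temperature = paste(num(cfg$body_temperature), "K"),
    duration = paste(num(cfg$duration), "s"),
    snapshot_times = vapply(cfg$snapshot_times, num, character(1)),
    geometry = lapply(unclass(cfg$geometry), num),
    properties = lapply(unclass(cfg$properties), function(x) as.numeric(x)),
    rheology = lapply(unclass(cfg$rheology), function(x) as.numeric(x)),
    numerics = lapply(unclass(cfg$numerics), function(x) as.numeric(x))
  )
}

list_to_cfg <- function(lst) {
  geo <- if (is.null(lst$geometry)) vein_geometry() else do.call(vein_geometry, lst$geometry)
  pr <- if (is.null(lst$properties)) material_properties() else do.call(material_properties, lapply(lst$properties, as.numeric))
  rh <- if (is.null(lst$rheology)) carreau_yasuda() else do.call(carreau_yasuda, lapply(lst$rheology, as.numeric))
  nu <- if (is.null(lst$numerics)) solver_settings() else do.call(solver_settings, lapply(lst$numerics, as.numeric))
  scenario_config(
    inlet_velocity = lst$inlet_velocity %||% 0,
    pullback_velocity = lst$pullback_velocity %||% 0,
    electrode_temperature = lst$electrode_temperature %||% 358,
    body_temperature = lst$body_temperature %||% 309.15,
    duration = lst$duration %||% 7,
    snapshot_times = if (is.null(lst$snapshot_times)) NULL else as.list(lst$snapshot_times),
    geometry = geo, properties = pr, rheology = rh, numerics = nu,
    id = lst$id
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scenario configuration file
#'
#' Scenarios are stored as YAML with explicit unit suffixes; numbers are
#' formatted so that a write/read round trip reproduces the configuration
#' exactly.
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `read_scenario` returns a validated [scenario_config()];
#'   `write_scenario` returns `path` invisibly.
#' @export
write_scenario <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(cfg_to_list(cfg), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  list_to_cfg(yaml::read_yaml(path))
}

#' Read a scenario-matrix file
#'
#' A matrix file carries `U_list` and `V_list` entries (each a list of
#' velocities, unit strings allowed) next to the usual scenario fields; it
#' expands to the cross product of the two lists.
#'
#' @param path file path.
#' @return list of validated [scenario_config()] objects.
#' @export
read_scenario_matrix <- function(path) {
  lst <- yaml::read_yaml(path)
  U <- vapply(lst$U_list %||% list(0), parse_quantity, numeric(1),
              kind = "velocity", field = "U_list")
  V <- vapply(lst$V_list %||% list(0), parse_quantity, numeric(1),
              kind = "velocity", field = "V_list")
  lst$U_list <- NULL; lst$V_list <- NULL
  grid <- expand.grid(U = U, V = V, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(k) {
    lst$inlet_velocity <- grid$U[k]
    lst$pullback_velocity <- grid$V[k]
    lst$id <- NULL
    list_to_cfg(lst)
  })
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config '%s'>\n", x$id))
  cat(sprintf("  U = %g mm/s, V = %g mm/s, T_e = %g K, T_body = %g K, %g s\n",
              x$inlet_velocity * 1e3, x$pullback_velocity * 1e3,
              x$electrode_temperature, x$body_temperature, x$duration))
  invisible(x)
}
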