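#' Run a full transient ablation scenario
#'
#' Integrates the conjugate bioheat equation from a uniform
#' body-temperature initial condition, with the electrode held at its
#' surface temperature from the first step and withdrawn continuously at
#' the pullback velocity.  The quasi-steady flow field is re-solved
#' whenever the electrode occupancy mask has shifted by at least
#' `flow_update_rows` axial cell rows (warm-started from the previous
#' solution); the implicit heat operator is re-factorized at every mask or
#' time-step change.  Snapshots are recorded at the requested times and at
#' the final time.
#'
#' If pullback would carry the electrode out of the domain before
#' `duration`, the run is truncated at the exit time with a warning.
#'
#' @param cfg a [scenario_config()].
#' @param mesh optional pre-built mesh (defaults to `build_mesh` on the
#'   scenario geometry and numerics).
#' @param progress emit per-epoch progress messages to `stderr`.
#' @return an object of class `rfa_run`: the scenario, mesh, a list of
#'   [temperature_field()] snapshots with their `times`, the last
#'   `flow_field`, and `diagnostics` (flow solves, maximum energy-audit
#'   residual, maximum relative flow divergence, truncation flag).
#' @export
run_transient <- function(cfg, mesh = NULL, progress = FALSE) {
  cfg <- validate_config(cfg)
  if (is.null(mesh))
    mesh <- build_mesh(cfg$geometry, cfg$numerics$nr, cfg$numerics$nz)
  U <- cfg$inlet_velocity; V <- cfg$pullback_velocity
  Tb <- cfg$body_temperature; Te <- cfg$electrode_temperature
  props <- cfg$properties
  z0 <- cfg$geometry$electrode_start_z
  L_e <- cfg$geometry$electrode_length

  truncated <- FALSE
  t_end <- cfg$duration
  if (V > 0 && z0 / V < cfg$duration - 1e-12) {
    t_end <- z0 / V
    truncated <- TRUE
    warning(sprintf("electrode reaches the inlet at t = %.3g s; run truncated", t_end))
  }

  snap_times <- cfg$snapshot_times[cfg$snapshot_times <= t_end + 1e-12]
  snapshots <- list()
  times <- numeric(0)
  take_snap <- function(Tm, tt) {
    snapshots[[length(snapshots) + 1L]] <<- temperature_field(Tm, mesh, tt)
    times <<- c(times, tt)
  }

  Tm <- matrix(Tb, mesh$nr, mesh$nz)
  if (any(abs(snap_times - 0) < 1e-12)) take_snap(Tm, 0)
  if (t_end <= 0) {
    if (!length(snapshots)) take_snap(Tm, 0)
    return(structure(list(cfg = cfg, mesh = mesh, snapshots = snapshots,
                          times = times, flow = NULL,
                          diagnostics = list(flow_solves = 0L,
                                             max_energy_residual = 0,
                                             max_div_rel = 0,
                                             truncated = truncated)),
                     class = "rfa_run"))
  }

  # epoch boundaries: every axial mask change (cell centres crossing either
  # electrode end), every snapshot time, and the final time
  ev <- c(snap_times, t_end)
  if (V > 0) {
    cross <- c((z0 - mesh$z_c) / V, (z0 + L_e - mesh$z_c) / V)
    ev <- c(ev, cross[cross > 1e-12 & cross < t_end - 1e-12])
  }
  ev <- sort(unique(round(ev[ev > 1e-12], 12)))
  # drop events separated by less than 1 ns to avoid degenerate epochs
  ev <- ev[c(TRUE, diff(ev) > 1e-9)]
  if (abs(ev[length(ev)] - t_end) > 1e-9) ev <- c(ev, t_end)

  settings <- cfg$numerics
  state0 <- electrode_state(z0, V, Te)
  mask <- electrode_mask_at(mesh, state0)
  flow <- solve_flow(mesh, props, cfg$rheology, U,
                     electrode = state0, settings = settings)
  n_flow <- 1L
  jp_at_solve <- mask_lead_row(mask)
  cache <- NULL
  max_resid <- 0
  max_div <- flow$div_rel
  t_prev <- 0

  for (t_next in ev) {
    state <- electrode_state(z0 - V * t_prev, V, Te)
    mask_now <- electrode_mask_at(mesh, state)
    mask_changed <- !identical(mask_now, mask)
    if (mask_changed) {
      mask <- mask_now
      jp <- mask_lead_row(mask)
      if (!is.na(jp) && !is.na(jp_at_solve) &&
          abs(jp - jp_at_solve) >= settings$flow_update_rows) {
        st_mid <- electrode_state(z0 - V * t_prev, V, Te)
        flow <- solve_flow(mesh, props, cfg$rheology, U, electrode = st_mid,
                           settings = settings, init = flow)
        n_flow <- n_flow + 1L
        jp_at_solve <- jp
        max_div <- max(max_div, flow$div_rel)
      }
    }
    # time step for this epoch: advective CFL against the current flow
    umax_z <- max(abs(flow$uz)); umax_r <- max(abs(flow$ur))
    dt_allow <- min(settings$dt_max,
                    if (umax_z > 0) settings$cfl_limit * mesh$dz / umax_z else Inf,
                    if (umax_r > 0) settings$cfl_limit * min(mesh$dr) / umax_r else Inf)
    len <- t_next - t_prev
    nsteps <- max(1L, as.integer(ceiling(len / dt_allow - 1e-12)))
    dt <- len / nsteps
    if (is.null(cache) || mask_changed || abs(dt - cache$dt) > 1e-15)
      cache <- make_heat_cache(mesh, props, mask, U, dt, Tb, Te,
                               settings$q_rf_volumetric)
    for (s in seq_len(nsteps)) {
      out <- heat_step_core(Tm, flow, mesh, props, cache, settings$cfl_limit)
      check_max_principle(Tm, out$T, cfg, TRUE)
      Tm <- out$T
      max_resid <- max(max_resid, abs(out$audit[["residual_rel"]]))
    }
    if (progress)
      message(sprintf("t = %.3f s  Tmax = %.2f K  (dt = %.2g ms, %d flow solves)",
                      t_next, max(Tm), dt * 1e3, n_flow))
    if (any(abs(snap_times - t_next) < 1e-9) || abs(t_next - t_end) < 1e-9) {
      if (!length(times) || abs(times[length(times)] - t_next) > 1e-9)
        take_snap(Tm, t_next)
    }
    t_prev <- t_next
  }

  structure(list(cfg = cfg, mesh = mesh, snapshots = snapshots, times = times,
                 flow = flow,
                 diagnostics = list(flow_solves = n_flow,
                                    max_energy_residual = max_resid,
                                    max_div_rel = max_div,
                                    truncated = truncated)),
            class = "rfa_run")
}

# Leading (inlet-side) axial row index of the electrode mask.
mask_lead_row <- function(mask) {
  cols <- which(colSums(mask) > 0)
  if (!length(cols)) NA_integer_ else cols[1]
}

#' Extract the snapshot closest to a requested time
#'
#' @param run an `rfa_run`.
#' @param time requested time (s).
#' @param tol matching tolerance (s).
#' @return a [temperature_field()].
#' @export
snapshot_at <- function(run, time, tol = 1e-6) {
  k <- which.min(abs(run$times - time))
  if (abs(run$times[k] - time) > tol)
    stop(sprintf("no snapshot at t = %g s (available: %s)", time,
                 paste(signif(run$times, 4), collapse = ", ")))
  run$snapshots[[k]]
}

#' @export
print.rfa_run <- function(x, ...) {
  cat(sprintf("<rfa_run '%s': %d snapshots to t = %.3g s, %d flow solves%s>\n",
              x$cfg$id, length(x$snapshots), max(c(0, x$times)),
              x$diagnostics$flow_solves,
              if (x$diagnostics$truncated) ", truncated" else ""))
  invisible(x)
}
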