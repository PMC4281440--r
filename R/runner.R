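#' Run a single scenario end-to-end with file outputs
#'
#' Integrates the scenario, computes a [metrics_report()] for every
#' snapshot and, when `out_dir` is given, writes per-snapshot VTK files,
#' interface-profile and centreline CSVs, a JSON metrics file and returns
#' everything in memory as well.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory (created if needed), or `NULL` for an
#'   in-memory run without file output.
#' @param write_vtk write VTK snapshot files (can be disabled to keep
#'   matrix sweeps lean).
#' @return list with the `rfa_run`, the per-snapshot `metrics` list and
#'   the vector of written `files`.
#' @export
run_scenario <- function(cfg, out_dir = NULL, write_vtk = TRUE) {
  cfg <- validate_config(cfg)
  run <- run_transient(cfg)
  metrics <- lapply(run$snapshots, metrics_report, mesh = run$mesh, cfg = cfg)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(run$snapshots)) {
      Tf <- run$snapshots[[k]]
      tag <- sprintf("%s_t%05.0fms", cfg$id, Tf$time * 1e3)
      if (write_vtk) {
        f <- file.path(out_dir, paste0(tag, ".vtk"))
        write_vtk_snapshot(run$mesh, list(temperature_K = Tf$T), f,
                           title = sprintf("%s t=%gs", cfg$id, Tf$time))
        files <- c(files, f)
      }
      f <- file.path(out_dir, paste0(tag, "_interface.csv"))
      write_interface_csv(extract_interface_profile(Tf, run$mesh, cfg$properties), f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, paste0(cfg$id, "_metrics.json"))
    jsonlite::write_json(lapply(metrics, unclass), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  list(run = run, metrics = metrics, files = files)
}

#' Run a scenario matrix
#'
#' Executes every scenario (for example the inlet-velocity sweep crossed
#' with the pullback velocities), collecting per-scenario metrics into a
#' manifest.  A failing scenario is recorded in the manifest and the
#' remaining scenarios still run.  The pipeline contains no random number
#' generation: a rerun of the same configuration reproduces the manifest
#' and summary exactly.
#'
#' @param configs list of [scenario_config()] objects (or a matrix-file
#'   path accepted by [read_scenario_matrix()]).
#' @param out_dir optional output directory for per-scenario files.
#' @param write_vtk passed to [run_scenario()].
#' @return an object of class `run_manifest`: per-scenario status, output
#'   paths, metrics, the configuration hash and wall-clock seconds.
#' @export
run_matrix <- function(configs, out_dir = NULL, write_vtk = FALSE) {
  if (is.character(configs)) configs <- read_scenario_matrix(configs)
  t0 <- Sys.time()
  results <- list()
  for (cfg in configs) {
    cfg <- validate_config(cfg)
    res <- tryCatch(
      {
        out <- run_scenario(cfg, out_dir = out_dir, write_vtk = write_vtk)
        list(id = cfg$id, status = "ok", cfg = cfg,
             metrics = out$metrics, files = out$files,
             diagnostics = out$run$diagnostics)
      },
      error = function(e) list(id = cfg$id, status = "error", cfg = cfg,
                               message = conditionMessage(e),
                               metrics = list(), files = character(0)))
    results[[cfg$id]] <- res
  }
  structure(list(results = results,
                 config_hash = rlang::hash(lapply(configs, cfg_to_list)),
                 version = as.character(utils::packageVersion("rfavein")),
                 wall_clock_s = as.numeric(Sys.time() - t0, units = "secs"),
                 out_dir = out_dir),
            class = "run_manifest")
}

#' Summarize a run manifest into a tidy table
#'
#' One row per (scenario, snapshot time), with the headline metrics.
#' Deterministic: identical configurations yield identical tables.
#'
#' @param manifest a `run_manifest` from [run_matrix()].
#' @return data.frame with columns `scenario`, `U_mm_s`, `V_mm_s`,
#'   `time_s`, `peak_interface_T_K`, `peak_z_mm`, `max_domain_T_K`,
#'   `influenced_fraction`, `damage_fraction_313K`,
#'   `irreversible_fraction_323K`, `wall_energy_J`.
#' @export
summarize_runs <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  bad <- vapply(manifest$results, function(r) r$status != "ok", logical(1))
  if (any(bad))
    stop("missing outputs for scenarios: ",
         paste(names(manifest$results)[bad], collapse = ", "))
  rows <- lapply(manifest$results, function(r) {
    do.call(rbind, lapply(r$metrics, function(m)
      data.frame(scenario = r$id,
                 U_mm_s = r$cfg$inlet_velocity * 1e3,
                 V_mm_s = r$cfg$pullback_velocity * 1e3,
                 time_s = m$time,
                 peak_interface_T_K = m$peak_interface_T,
                 peak_z_mm = m$peak_interface_z * 1e3,
                 max_domain_T_K = m$max_domain_T,
                 influenced_fraction = m$influenced_fraction,
                 damage_fraction_313K = m$damage_fraction_313K,
                 irreversible_fraction_323K = m$irreversible_fraction_323K,
                 wall_energy_J = m$wall_energy_J)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(scenario = character(0), U_mm_s = numeric(0),
                      V_mm_s = numeric(0), time_s = numeric(0),
                      peak_interface_T_K = numeric(0), peak_z_mm = numeric(0),
                      max_domain_T_K = numeric(0),
                      influenced_fraction = numeric(0),
                      damage_fraction_313K = numeric(0),
                      irreversible_fraction_323K = numeric(0),
                      wall_energy_J = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write an axisymmetric snapshot as a legacy-ASCII VTK structured grid
#'
#' Points are laid out as (z, r, 0); per-cell fields are written as
#' `CELL_DATA` scalars.  Intended for inspection in ParaView etc.
#'
#' @param mesh the mesh.
#' @param fields named list of `nr x nz` matrices.
#' @param path output file.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(mesh, fields, path, title = "rfavein snapshot") {
  nr <- mesh$nr; nz <- mesh$nz
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("%s", title)
  wl("ASCII")
  wl("DATASET STRUCTURED_GRID")
  wl("DIMENSIONS %d %d 1", nz + 1L, nr + 1L)
  wl("POINTS %d double", (nz + 1L) * (nr + 1L))
  pts <- expand.grid(z = mesh$z_faces, r = mesh$r_faces)
  writeLines(sprintf("%.9g %.9g 0", pts$z, pts$r), con)
  wl("CELL_DATA %d", nr * nz)
  for (nm in names(fields)) {
    wl("SCALARS %s double 1", nm)
    wl("LOOKUP_TABLE default")
    # VTK cell ordering: fastest along the first (z) dimension
    writeLines(sprintf("%.9g", as.numeric(t(fields[[nm]]))), con)
  }
  invisible(path)
}

#' Write an interface profile as CSV
#'
#' @param profile an `interface_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interface_csv <- function(profile, path) {
  utils::write.csv(data.frame(z_mm = profile$z * 1e3, T_K = profile$T),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  ok <- sum(vapply(x$results, function(r) r$status == "ok", logical(1)))
  cat(sprintf("<run_manifest: %d/%d scenarios ok, hash %s, %.1f s>\n",
              ok, length(x$results), substr(x$config_hash, 1, 8),
              x$wall_clock_s))
  invisible(x)
}
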