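# Shared test helpers: small grids and a memoised reduced transient run.

small_numerics <- function(...) solver_settings(nr = 19L, nz = 60L, ...)

newtonian_cy <- function(mu = 0.0035) carreau_yasuda(mu_inf = mu, mu_0 = mu * (1 + 1e-9))

# a hand-built staggered field (plug flow) for operator-level tests
plug_flow <- function(mesh, u0) {
  list(uz = matrix(u0, mesh$nr, mesh$nz + 1L),
       ur = matrix(0, mesh$nr + 1L, mesh$nz),
       solid = matrix(FALSE, mesh$nr, mesh$nz), U = u0, V = 0)
}

.run_cache <- new.env(parent = emptyenv())

# memoised reduced pullback run used by several test files
cached_reduced_run <- function(U = 0, V = 1e-3, duration = 3,
                               nr = 19L, nz = 120L) {
  key <- paste("red", U, V, duration, nr, nz, sep = "_")
  if (is.null(.run_cache[[key]])) {
    cfg <- scenario_config(inlet_velocity = U, pullback_velocity = V,
                           duration = duration,
                           numerics = solver_settings(nr = nr, nz = nz))
    .run_cache[[key]] <- run_transient(cfg)
  }
  .run_cache[[key]]
}
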