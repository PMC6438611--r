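# Shared, lazily computed simulation runs: the full-cycle scenarios are
# expensive, so they are computed once per test session and reused across
# test files.

# report every expectation rather than aborting the session early
options(testthat.progress.max_fails = 1000L)

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

scenario_history <- function(sc, ...) {
  cached(paste0("hist_", sc),
         run_breathing_cycle(sc, coupling_config(...), n_cycles = 2))
}

scenario_report <- function(sc) {
  cached(paste0("rep_", sc), lung_function_report(scenario_history(sc)))
}

healthy_geometry <- function() {
  cached("geom_healthy", apply_scenario(assemble_acinus(), "healthy"))
}

# a synthetic history with prescribed volume/pressure traces (for metric
# unit tests that need a known ground truth)
synthetic_history <- function(volume, p_ip, dt = 0.01, V0 = volume[1]) {
  n <- length(volume)
  tt <- seq(0, by = dt, length.out = n)
  flow <- c(0, diff(volume) / dt)
  df <- data.frame(time = tt, p_ip = p_ip, volume = volume, flow = flow,
                   p_drop = -0.1 * flow, p_alv = -0.05 * flow,
                   u_max = abs(flow), wss_max = abs(flow) * 1e-3,
                   smax_primary = 0, smax_secondary = 0,
                   subiters = 1L, newton_iters = 1L, resid = 0)
  structure(list(df = df, V0 = V0,
                 scenario = scenario_presets()$healthy,
                 config = coupling_config(dt = dt),
                 period = (n - 1) * dt, n_cycles = 1L),
            class = "state_history")
}

# shared time-convergence study (higher-viscosity variant; see the methods
# vignette): returns the observed order of the volume trajectory
dt_convergence_order <- function() {
  cached("dt_order", {
    run_dt <- function(dt) {
      cfg <- coupling_config(dt = dt, newton_tol = 1e-10, tol = 1e-8,
                             max_subiter = 80L,
                             props = fluid_properties(mu = 1.86e-5 * 500))
      utils::tail(run_breathing_cycle("healthy", cfg, t_end = 0.5)$df$volume,
                  1L)
    }
    v1 <- run_dt(0.02); v2 <- run_dt(0.01); v3 <- run_dt(0.005)
    log2(abs(v1 - v2) / abs(v2 - v3))
  })
}
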