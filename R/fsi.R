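# Partitioned two-way fluid-structure coupling over the breathing cycle.
#
# Per time step: the intrapleural pressure load is applied to the outer
# tissue surface; the quasi-static shell solve yields wall displacement and
# per-cell lumen volumes; compartment volume rates (BDF2 in time) drive the
# fluid solve, whose alveolar pressures are fed back onto the inner tissue
# surface; the exchange is sub-iterated (Gauss-Seidel with Aitken dynamic
# under-relaxation) until the interface displacement is stationary.  A
# loose-coupling switch performs a single exchange per step instead.

#' Sinusoidal intrapleural (breathing) waveform
#'
#' `p_IP(t) = -p0 (1/2 - 1/2 cos(omega t))`: zero at end-expiration (FRC),
#' `-p0` at end-inspiration, period `2 pi / omega`.
#'
#' @param p0 Pressure amplitude in Pa (244 Pa is about 2.5 cmH2O).
#' @param omega Circular frequency in 1/s (pi/2 gives the 4 s normal
#'   breathing period).
#' @return Object of class `breathing_waveform` with `p0`, `omega`, `period`.
#' @export
breathing_waveform <- function(p0 = 244, omega = pi / 2) {
  stopifnot(p0 >= 0, omega > 0)
  structure(list(p0 = p0, omega = omega, period = 2 * pi / omega),
            class = "breathing_waveform")
}

#' Intrapleural pressure at time t
#'
#' @param t Time in s (>= 0).
#' @param w A [breathing_waveform()].
#' @return Pressure in Pa, in `[-p0, 0]`.
#' @export
intrapleural_pressure <- function(t, w = breathing_waveform()) {
  stopifnot(all(t >= 0))
  -w$p0 * (0.5 - 0.5 * cos(w$omega * t))
}

#' Coupling configuration
#'
#' @param dt Time step in s (default 0.01).
#' @param n_cycles Number of breathing cycles (metrics use the last one).
#' @param tol Sub-iteration tolerance on the relative interface-displacement
#'   change.
#' @param max_subiter Maximum coupling sub-iterations per step.
#' @param loose If `TRUE`, one fluid/solid exchange per step (explicit
#'   staggering) instead of sub-iterations.
#' @param fluid_mode `"network"` (reduced Poiseuille network, default) or
#'   `"mesh3d"` (stabilised Stokes on the tetrahedral lumen mesh).
#' @param solid_mode `"shell"` (thin-shell septa; the only solid mode).
#' @param mesh_level Mesh refinement level (1-3).
#' @param newton_tol Relative residual tolerance of the solid solve.
#' @param waveform A [breathing_waveform()].
#' @param props A [fluid_properties()].
#' @param seed Integer seed recorded with the run (the solvers themselves
#'   are deterministic).
#' @return Object of class `coupling_config`.
#' @export
coupling_config <- function(dt = 0.01, n_cycles = 2L, tol = 1e-6,
                            max_subiter = 25L, loose = FALSE,
                            fluid_mode = c("network", "mesh3d"),
                            solid_mode = "shell", mesh_level = 1L,
                            newton_tol = 1e-8,
                            waveform = breathing_waveform(),
                            props = fluid_properties(), seed = 1L) {
  if (dt <= 0) stop_acinusim("dt must be positive", "acinusim_invalid_parameter")
  if (tol <= 0) stop_acinusim("tol must be positive", "acinusim_invalid_parameter")
  fluid_mode <- match.arg(fluid_mode)
  structure(list(dt = dt, n_cycles = as.integer(n_cycles), tol = tol,
                 max_subiter = as.integer(max_subiter), loose = loose,
                 fluid_mode = fluid_mode, solid_mode = solid_mode,
                 mesh_level = as.integer(mesh_level),
                 newton_tol = newton_tol, waveform = waveform,
                 props = props, seed = as.integer(seed)),
            class = "coupling_config")
}

#' Move a fluid volume mesh to follow boundary displacement
#'
#' Interior nodes are relocated by an elliptic (graph-Laplacian) smoothing
#' solve of the mesh displacement equations; element inversion raises a
#' step-size-reduction request.
#'
#' @param mesh A `fluid_mesh`.
#' @param boundary_disp n x 3 displacement matrix; only rows of boundary
#'   nodes (`wall_nodes` and `open_nodes`) are used.
#' @return The moved `fluid_mesh`.
#' @export
move_fluid_mesh <- function(mesh, boundary_disp) {
  n <- nrow(mesh$nodes)
  bnd <- sort(unique(c(mesh$wall_nodes, mesh$open_nodes)))
  inner <- setdiff(seq_len(n), bnd)
  disp <- matrix(0, n, 3L)
  disp[bnd, ] <- as.matrix(boundary_disp)[bnd, , drop = FALSE]
  if (length(inner)) {
    ed <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)],
                mesh$tets[, c(1, 4)], mesh$tets[, c(2, 3)],
                mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
    ed <- unique(rbind(ed, ed[, 2:1]))
    L <- sparseMatrix(i = ed[, 1], j = ed[, 2], x = -1, dims = c(n, n))
    deg <- -Matrix::rowSums(L)
    L <- L + Diagonal(n, deg)
    for (k in 1:3) {
      rhs <- -as.numeric(L[inner, bnd, drop = FALSE] %*% disp[bnd, k])
      disp[inner, k] <- as.numeric(Matrix::solve(L[inner, inner], rhs))
    }
  }
  out <- mesh
  out$nodes <- mesh$nodes + disp
  vol <- tet_volumes(out$nodes, out$tets)
  if (any(vol <= 0)) {
    stop_acinusim("mesh motion inverted elements; reduce the step size",
                  "acinusim_mesh_inversion", elements = which(vol <= 0))
  }
  out
}

# ---- coupled system --------------------------------------------------------

#' Initialise the coupled fluid-solid system for a scenario
#'
#' Builds the calibrated geometry, the shell solid, the duct network (and the
#' tetrahedral lumen mesh in `mesh3d` mode) and returns the initial resting
#' state.
#'
#' @param scenario A [disease_scenario()] or preset name.
#' @param config A [coupling_config()].
#' @return Object of class `simulation_state` at t = 0.
#' @export
fsi_init <- function(scenario, config = coupling_config()) {
  scenario <- as_disease_scenario(scenario)
  geom <- apply_scenario(assemble_acinus(), scenario)
  solid <- build_shell_mesh(geom, level = config$mesh_level)
  mat <- neo_hookean(scenario$E, scenario$nu)
  network <- acinus_network(geom, config$props)
  fluid3d <- if (config$fluid_mode == "mesh3d") {
    build_fluid_mesh(geom, level = config$mesh_level)
  } else NULL
  sys <- list(geom = geom, solid = solid, mat = mat, network = network,
              fluid3d = fluid3d, config = config,
              cache = new.env(parent = emptyenv()),
              n_cells = nrow(geom$cells),
              is_primary = solid$tri_class == "primary",
              cell1 = solid$tri_cell1, cell2 = solid$tri_cell2)
  # force-norm floor for the solid residual scale: the waveform crosses
  # zero load, where a purely relative tolerance is ill-posed; anchor it at
  # 0.1% of the load-amplitude force norm
  pre0 <- .shell_precompute(solid, mat)
  sys$cache$pre <- pre0
  q1 <- as.numeric(sys$is_primary)
  sys$fscale_min <- 1e-3 * config$waveform$p0 *
    .shell_grad(solid$nodes, solid, pre0, q1)$fext
  Vk <- cell_volumes(solid)
  structure(list(
    sys = sys, t = 0, x = solid$nodes,
    Vk = Vk, Vk_prev = Vk, Q = 0, P_A = numeric(sys$n_cells),
    step = 0L, st = NULL
  ), class = "simulation_state")
}

# per-triangle follower traction from intrapleural + alveolar pressures
.tri_loads <- function(sys, p_ip, P_A) {
  q <- numeric(length(sys$cell1))
  prim <- sys$is_primary
  q[prim] <- P_A[sys$cell1[prim]] - p_ip
  sec <- !prim
  q[sec] <- P_A[sys$cell1[sec]] - P_A[sys$cell2[sec]]
  q
}

#' Advance the coupled state by one time step
#'
#' @param state A `simulation_state`.
#' @param dt Time step in s (defaults to the configured dt).
#' @param config Optional [coupling_config()] overriding the system's.
#' @return Updated `simulation_state`; per-step scalars in `state$scalars`.
#' @export
fsi_step <- function(state, dt = NULL, config = NULL) {
  sys <- state$sys
  cfg <- config %||% sys$config
  dt <- dt %||% cfg$dt
  t_new <- state$t + dt
  p_ip <- intrapleural_pressure(t_new, cfg$waveform)
  # linear-in-time predictors: warm-start the solid at the extrapolated
  # wall position and the fluid exchange at the extrapolated alveolar
  # pressure (the sub-iteration still verifies convergence)
  P_A <- if (!is.null(state$P_A_prev)) 2 * state$P_A - state$P_A_prev else
    state$P_A
  x <- if (!is.null(state$x_prev)) 2 * state$x - state$x_prev else state$x
  omega_r <- 0.8
  r_prev <- NULL
  n_sub <- 0L
  resid <- NA_real_
  newton_it <- 0L
  dVdt_k <- NULL
  flow <- NULL
  max_sub <- if (cfg$loose) 1L else cfg$max_subiter
  uscale <- max(sqrt(rowSums((x - sys$solid$nodes)^2)), 1e-6)
  repeat {
    n_sub <- n_sub + 1L
    q <- .tri_loads(sys, p_ip, P_A)
    st <- solve_quasistatic(sys$solid, sys$mat, bc = list(q = q),
                            prior = list(x = x),
                            control = list(tol = cfg$newton_tol,
                                           fscale_min = sys$fscale_min,
                                           refresh = (n_sub == 1L &&
                                                      state$step %% 20L == 0L),
                                           cache = sys$cache))
    newton_it <- newton_it + st$iterations
    x_new <- st$x
    Vk_new <- cell_volumes(sys$solid, x_new)
    dVdt_k <- if (state$step == 0L) {
      2 * (Vk_new - state$Vk) / dt - 0      # trapezoidal start, dV/dt(0) = 0
    } else {
      (3 * Vk_new - 4 * state$Vk + state$Vk_prev) / (2 * dt)
    }
    flow <- .fluid_solve(sys, cfg, x_new, dVdt_k, dt)
    P_A_cand <- flow$P_A
    resid <- max(abs(x_new - x)) / max(uscale, max(abs(x_new - sys$solid$nodes)))
    x <- x_new
    # converged when the interface displacement is stationary, or when the
    # pending alveolar-pressure update is already below tolerance relative
    # to the driving load (its displacement effect is then below tol too)
    dPA <- max(abs(P_A_cand - P_A)) / max(abs(p_ip), 1)
    if (cfg$loose || resid < cfg$tol || dPA < cfg$tol || n_sub >= max_sub) {
      P_A <- P_A_cand
      break
    }
    r <- P_A_cand - P_A
    if (!is.null(r_prev)) {
      dr <- r - r_prev
      den <- sum(dr^2)
      if (den > 0) omega_r <- -omega_r * sum(r_prev * dr) / den
      omega_r <- min(max(omega_r, 0.02), 1.5)
    }
    P_A <- P_A + omega_r * r
    r_prev <- r
  }
  if (!cfg$loose && n_sub >= max_sub && resid >= cfg$tol) {
    stop_acinusim(sprintf(
      "coupling sub-iterations did not converge (residual %.2e)", resid),
      "acinusim_coupling_failure", residual = resid)
  }
  mps <- max_principal_stress(st)
  V_new <- sum(Vk_new)
  scal <- data.frame(
    time = t_new, p_ip = p_ip, volume = V_new,
    flow = sum(dVdt_k),
    p_drop = flow$p_drop, p_alv = flow$p_alv,
    u_max = flow$u_max, wss_max = flow$wss_max,
    smax_primary = unname(mps$by_class["primary"] %||% NA_real_),
    smax_secondary = if ("secondary" %in% names(mps$by_class))
      unname(mps$by_class[["secondary"]]) else NA_real_,
    subiters = n_sub, newton_iters = newton_it, resid = resid
  )
  state$t <- t_new
  state$x_prev <- state$x
  state$P_A_prev <- state$P_A
  state$x <- x
  state$Vk_prev <- state$Vk
  state$Vk <- Vk_new
  state$Q <- sum(dVdt_k)
  state$P_A <- P_A
  state$step <- state$step + 1L
  state$st <- st
  state$scalars <- scal
  state
}

# fluid sub-solve: returns per-cell alveolar pressures and step scalars
.fluid_solve <- function(sys, cfg, x_new, dVdt_k, dt) {
  if (cfg$fluid_mode == "network") {
    nf <- duct_network_flow(sys$network, dVdt_k)
    umax <- max(abs(nf$edge_flow) / (pi * sys$network$edges$r_eq^2))
    wss <- max(4 * cfg$props$mu * abs(nf$edge_flow) /
                 (pi * sys$network$edges$r_eq^3))
    pd <- nf$p[which.max(abs(nf$p))]
    alv <- sys$geom$cells$type == "alveolus"
    list(P_A = nf$p, p_drop = pd,
         p_alv = sum(nf$p[alv] * sys$geom$cells$volume[alv]) /
           sum(sys$geom$cells$volume[alv]),
         u_max = umax, wss_max = wss, flow = nf)
  } else {
    # mesh3d: move the lumen mesh with the wall, solve Stokes with the wall
    # velocity, read back per-cell mean pressures
    fm <- sys$fluid3d
    if (is.null(sys$cache$imap)) {
      sys$cache$imap <- build_interface_map(sys$solid$nodes, fm$nodes)
      sys$cache$cell_of_tet <- fm$tet_cell
    }
    disp_t <- transfer_displacement(sys$cache$imap, x_new - sys$solid$nodes)
    moved <- move_fluid_mesh(fm, disp_t)
    uprev <- sys$cache$fm_disp %||% (disp_t * 0)
    wallv <- (disp_t - uprev) / dt
    fl <- solve_low_re_flow(moved, wallv, cfg$props)
    sys$cache$fm_disp <- disp_t
    # per-cell mean pressure (tets were coned cell-by-cell in build order)
    gr <- .tet_grads(moved$nodes, moved$tets)
    pe <- (fl$p[moved$tets[, 1]] + fl$p[moved$tets[, 2]] +
           fl$p[moved$tets[, 3]] + fl$p[moved$tets[, 4]]) / 4
    P_A <- as.numeric(tapply(pe * gr$vol, sys$cache$cell_of_tet, sum) /
                        tapply(gr$vol, sys$cache$cell_of_tet, sum))
    wssl <- wall_shear_stress(fl)
    pd <- P_A[which.max(abs(P_A))]
    list(P_A = P_A, p_drop = pd, p_alv = mean(P_A),
         u_max = sqrt(max(rowSums(fl$u^2))), wss_max = wssl$max, flow = fl)
  }
}

#' Run breathing cycles for a scenario
#'
#' Advances the coupled system over `n_cycles` breathing periods starting
#' from the resting volume and collects the scalar history.
#'
#' @param scenario A [disease_scenario()] or preset name
#'   (`"healthy"`, `"nsip"`, `"ipf"`).
#' @param config A [coupling_config()].
#' @param n_cycles Number of cycles (defaults to the configured value).
#' @param t_end Optional early stop time in s (overrides `n_cycles`; used
#'   for time-step studies on a partial cycle).
#' @param verbose Print progress.
#' @return Object of class `state_history`: data frame `df` of per-step
#'   scalars, resting volume `V0`, scenario, config, and the periodicity
#'   check `cycle_tv_change`.
#' @export
run_breathing_cycle <- function(scenario, config = coupling_config(),
                                n_cycles = NULL, t_end = NULL,
                                verbose = FALSE) {
  scenario <- as_disease_scenario(scenario)
  n_cycles <- n_cycles %||% config$n_cycles
  state <- fsi_init(scenario, config)
  period <- config$waveform$period
  t_stop <- t_end %||% (n_cycles * period)
  n_steps <- round(t_stop / config$dt)
  rows <- vector("list", n_steps)
  V0 <- sum(state$Vk)
  for (i in seq_len(n_steps)) {
    state <- fsi_step(state)
    rows[[i]] <- state$scalars
    if (verbose && i %% 50L == 0L) {
      message(sprintf("t=%.2f s V=%.5f Q=%+.4f", state$t,
                      state$scalars$volume, state$scalars$flow))
    }
  }
  df <- do.call(rbind, rows)
  df <- rbind(data.frame(time = 0, p_ip = 0, volume = V0, flow = 0,
                         p_drop = 0, p_alv = 0, u_max = 0, wss_max = 0,
                         smax_primary = 0, smax_secondary = 0,
                         subiters = 0L, newton_iters = 0L, resid = 0), df)
  hist <- structure(list(
    df = df, V0 = V0, scenario = scenario, config = config,
    period = period, n_cycles = n_cycles, state = state
  ), class = "state_history")
  if (is.null(t_end) && n_cycles >= 2L) {
    tv <- vapply(seq_len(n_cycles), function(k) {
      sub <- df[df$time > (k - 1) * period + 1e-9 &
                df$time <= k * period + 1e-9, ]
      max(sub$volume) - V0
    }, numeric(1))
    hist$cycle_tv_change <- abs(tv[n_cycles] - tv[n_cycles - 1L]) /
      tv[n_cycles]
  }
  hist
}

#' Extract the last full breathing cycle of a history
#'
#' @param history A `state_history`.
#' @return The subset of `history$df` covering the final cycle.
#' @export
last_cycle <- function(history) {
  stopifnot(inherits(history, "state_history"))
  df <- history$df
  t_end <- max(df$time)
  df[df$time >= t_end - history$period - 1e-9, , drop = FALSE]
}

#' @export
print.state_history <- function(x, ...) {
  cat(sprintf(
    "<state_history: %s, %d steps over %.3g s, V0=%.4g mm^3, TV=%.4g mm^3>\n",
    x$scenario$name, nrow(x$df) - 1L, max(x$df$time), x$V0,
    max(last_cycle(x)$volume) - x$V0))
  invisible(x)
}
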