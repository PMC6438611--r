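# Incompressible low-Reynolds airflow in the lumen.
#
# Two modes:
#  * mesh3d — stabilised P1-P1 finite elements for the Stokes limit of the
#    incompressible Navier-Stokes equations on a tetrahedral mesh with
#    prescribed wall velocities and zero-pseudo-traction open boundaries
#    (Brezzi-Pitkaranta pressure stabilisation, direct sparse solve).  At the
#    breathing Reynolds number (~0.08) the convective and transient inertial
#    terms are negligible, so the quasi-steady Stokes system is the default;
#    this is the reference mode for field quantities (WSS, velocity fields).
#  * network — a Poiseuille/orifice duct network (Kirchhoff balance on a
#    conductance-weighted Laplacian), the fast reduced mode used for the
#    breathing-cycle runs and sweeps.

#' Air properties
#'
#' Humid air at body temperature (37 C) by default.  Density only enters the
#' Reynolds number and the (negligible) inertial terms; viscosity sets all
#' viscous scales.
#'
#' @param rho Density in kg/m^3.
#' @param mu Dynamic viscosity in Pa s.
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1.145, mu = 1.86e-5) {
  if (rho <= 0 || mu <= 0) {
    stop_acinusim("rho and mu must be positive", "acinusim_invalid_parameter")
  }
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

# ---- mesh3d: stabilised Stokes --------------------------------------------

# per-element shape gradients and volumes for P1 tets
.tet_grads <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  # inverse of J = [b; c; d] rows via adjugate
  det <- b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
         b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
         b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
  vol <- det / 6
  inv <- array(0, c(nrow(tets), 3L, 3L))
  inv[, 1, 1] <- (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) / det
  inv[, 1, 2] <- (b[, 3] * d[, 2] - b[, 2] * d[, 3]) / det
  inv[, 1, 3] <- (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) / det
  inv[, 2, 1] <- (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) / det
  inv[, 2, 2] <- (b[, 1] * d[, 3] - b[, 3] * d[, 1]) / det
  inv[, 2, 3] <- (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) / det
  inv[, 3, 1] <- (c_[, 1] * d[, 2] - c_[, 2] * d[, 1]) / det
  inv[, 3, 2] <- (b[, 2] * d[, 1] - b[, 1] * d[, 2]) / det
  inv[, 3, 3] <- (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]) / det
  # gradient of barycentric shapes: rows of inv give grad of local coords
  # grad phi_k (k=2..4) = inv[, ,k-1]; grad phi_1 = -sum
  g <- array(0, c(nrow(tets), 4L, 3L))
  for (k in 1:3) g[, k + 1L, ] <- inv[, , k]
  g[, 1L, ] <- -(g[, 2L, ] + g[, 3L, ] + g[, 4L, ])
  list(grad = g, vol = vol)
}

#' Solve incompressible low-Reynolds flow on a tetrahedral mesh
#'
#' Stabilised P1-P1 Stokes solve with no-slip walls (prescribed wall
#' velocity) and open boundaries at zero static pressure; optionally a
#' uniform pseudo-traction (pressure head) on named open patches.
#'
#' @param mesh A `fluid_mesh`.
#' @param wall_velocity n x 3 matrix of wall-node velocities (mm/s); scalar 0
#'   for stationary walls.  Only rows of `mesh$wall_nodes` are used.
#' @param props A [fluid_properties()].
#' @param open_pressure Named numeric: static pressure (Pa) imposed on open
#'   patches (e.g. `c(inlet = 1, outlet = 0)`); patches not named get 0.
#' @param stab Stabilisation coefficient (Brezzi-Pitkaranta), default 0.05.
#' @return Object of class `flow_field`: nodal `u` (mm/s), `p` (Pa), per
#'   patch volumetric `fluxes` (mm^3/s, positive out of the domain),
#'   `residual` of the discrete system.
#' @export
solve_low_re_flow <- function(mesh, wall_velocity = 0, props = fluid_properties(),
                              open_pressure = NULL, stab = 0.05) {
  nodes <- mesh$nodes; tets <- mesh$tets
  n <- nrow(nodes); m <- nrow(tets)
  mu <- props$mu
  gr <- .tet_grads(nodes, tets)
  if (any(gr$vol <= 0)) {
    stop_acinusim("inverted fluid elements", "acinusim_meshing_error")
  }
  # scalar stiffness K_ij = mu * sum_e vol * grad_i . grad_j
  idx <- expand.grid(a = 1:4, b = 1:4)
  ii <- as.vector(tets[, idx$a]); jj <- as.vector(tets[, idx$b])
  vv <- numeric(length(ii))
  pos <- 1L
  for (k in seq_len(nrow(idx))) {
    a <- idx$a[k]; b <- idx$b[k]
    vv[(pos):(pos + m - 1L)] <- mu * gr$vol *
      rowSums(gr$grad[, a, ] * gr$grad[, b, ])
    pos <- pos + m
  }
  Ks <- sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  # B_k[ip, jv] = -int phi_ip d(phi_jv)/dx_k  (continuity rows)
  Bk <- vector("list", 3L)
  for (k in 1:3) {
    vvb <- numeric(length(ii)); pos <- 1L
    for (r in seq_len(nrow(idx))) {
      a <- idx$a[r]; b <- idx$b[r]
      vvb[(pos):(pos + m - 1L)] <- -gr$vol / 4 * gr$grad[, b, k]
      pos <- pos + m
    }
    Bk[[k]] <- sparseMatrix(i = ii, j = jj, x = vvb, dims = c(n, n))
  }
  # pressure stabilisation
  h2 <- gr$vol^(2 / 3)
  vvc <- numeric(length(ii)); pos <- 1L
  for (k in seq_len(nrow(idx))) {
    a <- idx$a[k]; b <- idx$b[k]
    vvc[(pos):(pos + m - 1L)] <- stab * h2 / mu * gr$vol *
      rowSums(gr$grad[, a, ] * gr$grad[, b, ])
    pos <- pos + m
  }
  Cs <- sparseMatrix(i = ii, j = jj, x = vvc, dims = c(n, n))

  # full saddle system on [ux uy uz p]
  Z <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                    dims = c(n, n))
  A <- rbind(
    cbind(Ks, Z, Z, Matrix::t(Bk[[1]])),
    cbind(Z, Ks, Z, Matrix::t(Bk[[2]])),
    cbind(Z, Z, Ks, Matrix::t(Bk[[3]])),
    cbind(Bk[[1]], Bk[[2]], Bk[[3]], -Cs)
  )
  rhs <- numeric(4L * n)
  # open-boundary pseudo-traction -p_open * n_outward
  if (!is.null(open_pressure)) {
    for (lab in names(open_pressure)) {
      pb <- open_pressure[[lab]]
      if (pb == 0) next
      pt <- mesh$patches[mesh$patches$label == lab, , drop = FALSE]
      if (nrow(pt) == 0L) next
      tr <- as.matrix(pt[, c("n1", "n2", "n3")])
      e1 <- nodes[tr[, 2], , drop = FALSE] - nodes[tr[, 1], , drop = FALSE]
      e2 <- nodes[tr[, 3], , drop = FALSE] - nodes[tr[, 1], , drop = FALSE]
      cr <- .vcross(e1, e2) / 2          # area-weighted outward normal
      for (k in 1:3) {
        contrib <- rep(-pb * cr[, k] / 3, 3L)
        ids <- c(tr[, 1], tr[, 2], tr[, 3]) + (k - 1L) * n
        add <- rowsum(contrib, group = ids)
        rhs[as.integer(rownames(add))] <- rhs[as.integer(rownames(add))] + add
      }
    }
  }

  wall <- mesh$wall_nodes
  uw <- matrix(0, n, 3L)
  if (is.matrix(wall_velocity)) uw[wall, ] <- wall_velocity[wall, , drop = FALSE]
  known <- c(wall, wall + n, wall + 2L * n)
  xknown <- c(uw[wall, 1], uw[wall, 2], uw[wall, 3])
  free <- setdiff(seq_len(4L * n), known)
  rhs_f <- rhs[free] - as.numeric(A[free, known, drop = FALSE] %*% xknown)
  sol <- numeric(4L * n)
  sol[known] <- xknown
  sol[free] <- as.numeric(Matrix::solve(A[free, free], rhs_f))
  resid <- sqrt(sum((as.numeric(A[free, free] %*% sol[free]) - rhs_f)^2)) /
    max(sqrt(sum(rhs_f^2)), 1e-300)

  u <- cbind(sol[1:n], sol[(n + 1L):(2L * n)], sol[(2L * n + 1L):(3L * n)])
  p <- sol[(3L * n + 1L):(4L * n)]
  fluxes <- .patch_fluxes(mesh, u)
  structure(list(mesh = mesh, u = u, p = p, fluxes = fluxes,
                 props = props, residual = resid, mode = "mesh3d",
                 grads = gr), class = "flow_field")
}

# volumetric flux out of the domain through each patch label
.patch_fluxes <- function(mesh, u) {
  labs <- unique(mesh$patches$label)
  out <- setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    pt <- mesh$patches[mesh$patches$label == lab, , drop = FALSE]
    tr <- as.matrix(pt[, c("n1", "n2", "n3")])
    e1 <- mesh$nodes[tr[, 2], , drop = FALSE] - mesh$nodes[tr[, 1], , drop = FALSE]
    e2 <- mesh$nodes[tr[, 3], , drop = FALSE] - mesh$nodes[tr[, 1], , drop = FALSE]
    an <- .vcross(e1, e2) / 2
    um <- (u[tr[, 1], , drop = FALSE] + u[tr[, 2], , drop = FALSE] +
           u[tr[, 3], , drop = FALSE]) / 3
    out[lab] <- sum(rowSums(an * um))
  }
  out
}

#' Wall shear stress of a flow field
#'
#' For a 3D flow field: tangential component of the viscous traction
#' `mu (grad u + grad u') n` on each wall facet, from the adjacent element's
#' velocity gradient.  For a network flow: the Poiseuille wall shear
#' `4 mu Q / (pi r^3)` per edge.
#'
#' @param flow A `flow_field` or `network_flow`.
#' @return List with `per_facet` (Pa) and `max`.
#' @export
wall_shear_stress <- function(flow) {
  if (inherits(flow, "network_flow")) {
    tau <- 4 * flow$props$mu * abs(flow$edge_flow) / (pi * flow$network$edges$r_eq^3)
    return(list(per_facet = tau, max = max(tau)))
  }
  mesh <- flow$mesh
  pt <- mesh$patches[mesh$patches$label == "wall", , drop = FALSE]
  tr <- as.matrix(pt[, c("n1", "n2", "n3")])
  # adjacent tet per wall facet
  fk <- function(m) {
    m <- t(apply(m, 1L, sort)); paste(m[, 1], m[, 2], m[, 3])
  }
  tetf <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
                mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  tid <- rep(seq_len(nrow(mesh$tets)), 4L)
  keymap <- split(tid, fk(tetf))
  adj <- vapply(keymap[fk(tr)], `[`, integer(1), 1L)
  gr <- flow$grads %||% .tet_grads(mesh$nodes, mesh$tets)
  mu <- flow$props$mu
  e1 <- mesh$nodes[tr[, 2], , drop = FALSE] - mesh$nodes[tr[, 1], , drop = FALSE]
  e2 <- mesh$nodes[tr[, 3], , drop = FALSE] - mesh$nodes[tr[, 1], , drop = FALSE]
  cr <- .vcross(e1, e2)
  nrm <- cr / sqrt(rowSums(cr^2))
  tau <- numeric(nrow(tr))
  for (f in seq_len(nrow(tr))) {
    e <- adj[f]
    Gu <- matrix(0, 3L, 3L)  # Gu[i,j] = d u_i / d x_j
    for (k in 1:4) {
      Gu <- Gu + outer(flow$u[mesh$tets[e, k], ], gr$grad[e, k, ])
    }
    trac <- mu * (Gu + t(Gu)) %*% nrm[f, ]
    tt <- trac - sum(trac * nrm[f, ]) * nrm[f, ]
    tau[f] <- sqrt(sum(tt^2))
  }
  list(per_facet = tau, max = max(tau))
}

#' Reynolds number of a flow state
#'
#' `Re = rho |u|_max L / mu` with the characteristic length L (default the
#' 1 mm alveolar-sac length).  The peak velocity magnitude is taken over the
#' field's velocity representation: nodal velocities for a 3D solve,
#' cross-section mean velocities per edge for the duct network.
#'
#' @param flow A `flow_field` or `network_flow`, or a peak speed in mm/s.
#' @param L Characteristic length in mm.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow, L = 1.0) {
  if (inherits(flow, "flow_field")) {
    umax <- sqrt(max(rowSums(flow$u^2)))
    props <- flow$props
  } else if (inherits(flow, "network_flow")) {
    umax <- max(abs(flow$edge_flow) / (pi * flow$network$edges$r_eq^2))
    props <- flow$props
  } else {
    umax <- as.numeric(flow)
    props <- fluid_properties()
  }
  props$rho * (umax * 1e-3) * (L * 1e-3) / props$mu
}

# ---- duct network ----------------------------------------------------------

#' Construct a duct network
#'
#' Low-level constructor from an edge table; node 0 denotes the atmosphere
#' (zero-pressure reference outside the open boundary).
#'
#' @param edges Data frame with columns `from`, `to` (integer node ids, 0 =
#'   atmosphere), `g` (conductance, mm^3/s/Pa) and optionally `r_eq`
#'   (equivalent radius, mm).
#' @param n_nodes Number of interior nodes (compartments/junctions).
#' @param props A [fluid_properties()].
#' @return Object of class `duct_network`.
#' @export
duct_network <- function(edges, n_nodes, props = fluid_properties()) {
  stopifnot(all(c("from", "to", "g") %in% names(edges)))
  if (any(edges$g <= 0)) {
    stop_acinusim("conductances must be positive", "acinusim_invalid_parameter")
  }
  if (is.null(edges$r_eq)) edges$r_eq <- NA_real_
  net <- structure(list(edges = edges, n_nodes = as.integer(n_nodes),
                        props = props), class = "duct_network")
  # connectivity to the reference node
  reach <- .net_reachable(net)
  if (!all(seq_len(n_nodes) %in% reach)) {
    stop_acinusim("network has nodes disconnected from the open boundary",
                  "acinusim_invalid_parameter")
  }
  net
}

.net_reachable <- function(net) {
  adj <- rbind(net$edges[, c("from", "to")],
               setNames(net$edges[, c("to", "from")], c("from", "to")))
  seen <- 0L
  frontier <- 0L
  repeat {
    nxt <- unique(adj$to[adj$from %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Duct network of an acinus geometry
#'
#' One node per polyhedral cell plus the atmosphere; one edge per opening
#' (duct-path faces, alveolar mouths, open boundary).  Edge resistance is
#' the series sum of a Sampson orifice term `3 mu / r^3`, a channel term
#' `8 mu t / (pi r^4)` across the septal thickness t in which the opening
#' sits, and half-cell Poiseuille segments `8 mu l / (pi R^4)` on the
#' duct-type side(s) of the opening.
#'
#' @param geom An `acinus_geometry` with scenario applied.
#' @param props A [fluid_properties()].
#' @return A `duct_network` with nodes matching `geom$cells`.
#' @export
acinus_network <- function(geom, props = fluid_properties()) {
  stopifnot(inherits(geom, "acinus_geometry"), geom$kind == "acinus")
  mu <- props$mu
  fc <- geom$faces
  s <- geom$edge_length / sqrt(2)
  R_cell <- 2 * geom$edge_length / sqrt(pi)   # duct channel equivalent radius
  L_half <- 2 * s                             # half cell length on the lattice
  is_duct_cell <- geom$cells$type %in% c("parent", "duct")
  op <- which(fc$class %in% c("mouth", "duct", "open"))
  scn <- geom$scenario
  t_open <- scn$secondary_thickness %||% 0.025
  r_eq <- sqrt(fc$area[op] / pi)
  # Sampson orifice + channel-of-thickness-t resistance for the alveolar
  # mouths; duct-path faces are virtual cross-sections of the continuous
  # alveolar duct and the open boundary is an artificial truncation plane,
  # so both act as duct continuations at the channel calibre (no orifice)
  is_channel <- fc$class[op] %in% c("open", "duct")
  r_eq[is_channel] <- R_cell
  Rres <- ifelse(is_channel, 0,
                 3 * mu / r_eq^3 + 8 * mu * t_open / (pi * r_eq^4))
  from <- fc$cell1[op]
  to <- ifelse(is.na(fc$cell2[op]), 0L, fc$cell2[op])
  for (k in seq_along(op)) {
    for (cell in c(from[k], to[k])) {
      if (cell > 0L && is_duct_cell[cell]) {
        Rres[k] <- Rres[k] + 8 * mu * L_half / (pi * R_cell^4)
      }
    }
  }
  edges <- data.frame(from = from, to = to, g = 1 / Rres, r_eq = r_eq,
                      face_id = fc$id[op], kind = fc$class[op])
  duct_network(edges, n_nodes = nrow(geom$cells), props = props)
}

#' Solve the duct-network flow for given compartment volume rates
#'
#' Kirchhoff balance at every node: net outflow equals minus the compartment
#' volume rate, with the atmosphere at zero pressure.  Exact global mass
#' conservation: the open-boundary flux equals the summed volume rate.
#'
#' @param network A `duct_network`.
#' @param dVdt Numeric vector of compartment volume rates (mm^3/s), one per
#'   interior node (junctions without a compartment get 0).
#' @return Object of class `network_flow`: node pressures `p` (Pa, gauge),
#'   per-edge flows `edge_flow` (mm^3/s, from `from` to `to`), open-boundary
#'   flux `open_flux` (mm^3/s, positive out of the acinus).
#' @export
duct_network_flow <- function(network, dVdt) {
  ne <- network$edges
  n <- network$n_nodes
  dVdt <- rep_len(dVdt, n)
  ii <- c(ne$from, ne$to, ne$from, ne$to)
  jj <- c(ne$from, ne$to, ne$to, ne$from)
  vv <- c(ne$g, ne$g, -ne$g, -ne$g)
  # dropping the atmosphere row/column leaves the grounded Laplacian: the
  # retained (from, from) diagonal entries of boundary edges ground it
  keep <- ii > 0L & jj > 0L
  L <- sparseMatrix(i = ii[keep], j = jj[keep], x = vv[keep], dims = c(n, n))
  p <- as.numeric(Matrix::solve(L, -dVdt))
  pfrom <- ifelse(ne$from == 0L, 0, p[pmax(ne$from, 1L)])
  pto <- ifelse(ne$to == 0L, 0, p[pmax(ne$to, 1L)])
  q <- ne$g * (pfrom - pto)
  open_flux <- sum(q[ne$to == 0L]) - sum(q[ne$from == 0L])
  structure(list(network = network, p = p, edge_flow = q,
                 open_flux = open_flux, dVdt = dVdt,
                 props = network$props, mode = "network"),
            class = "network_flow")
}

#' Maximum pressure drop over a breathing history
#'
#' Cycle maximum of the interior-to-open-boundary pressure-drop magnitude,
#' evaluated on the last recorded cycle; the signed trace (negative during
#' inspiration, positive during expiration) is in the history itself.
#'
#' @param history A `state_history`.
#' @return Maximum |pressure drop| in Pa.
#' @export
max_pressure_drop <- function(history) {
  df <- last_cycle(history)
  max(abs(df$p_drop))
}
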