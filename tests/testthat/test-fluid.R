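# Low-Reynolds flow: stabilised Stokes solver and the duct network.

props19 <- fluid_properties(mu = 1.9e-5)

poiseuille_Q <- function(R, L, mu, dp) pi * R^4 * dp / (8 * mu * L)

test_that("stationary walls and zero forcing give a quiescent field", {
  tm <- tube_mesh(0.1, 0.5, n_r = 4L, n_theta = 12L, n_z = 4L)
  fl <- solve_low_re_flow(tm, 0, props19)
  expect_lt(max(abs(fl$u)), 1e-10)
  expect_lt(max(abs(fl$p)), 1e-8)
})

test_that("pressure-driven tube flow matches Hagen-Poiseuille within 3%", {
  tm <- cached("tube_poiseuille", tube_mesh(0.1, 1, n_r = 8L, n_theta = 24L,
                                            n_z = 8L))
  fl <- cached("flow_poiseuille",
               solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 1)))
  Qex <- poiseuille_Q(0.1, 1, 1.9e-5, 1)     # ~2.07 mm^3/s
  expect_equal(Qex, 2.0668, tolerance = 1e-4)
  expect_equal(unname(fl$fluxes["outlet"]), Qex, tolerance = 0.03)
  # in equals out (global mass conservation) within 0.5%
  expect_lt(abs(fl$fluxes[["inlet"]] + fl$fluxes[["outlet"]]) /
              abs(fl$fluxes[["outlet"]]), 0.005)
  # wall shear stress tau = 4 mu Q / (pi R^3) within 5%
  ws <- wall_shear_stress(fl)
  expect_lt(abs(ws$max / (4 * 1.9e-5 * Qex / (pi * 0.1^3)) - 1), 0.05)
})

test_that("Poiseuille error decreases monotonically under grid refinement", {
  Qex <- poiseuille_Q(0.1, 1, 1.9e-5, 1)
  errs <- vapply(list(c(4L, 12L, 4L), c(8L, 24L, 8L)), function(nn) {
    tm <- if (identical(nn, c(8L, 24L, 8L))) cached("tube_poiseuille",
      tube_mesh(0.1, 1, n_r = 8L, n_theta = 24L, n_z = 8L)) else
      tube_mesh(0.1, 1, n_r = nn[1], n_theta = nn[2], n_z = nn[3])
    fl <- if (identical(nn, c(8L, 24L, 8L))) cached("flow_poiseuille",
      solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 1))) else
      solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 1))
    abs(fl$fluxes[["outlet"]] / Qex - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("Stokes flow is linear and reversible in the driving", {
  tm <- tube_mesh(0.08, 0.5, n_r = 4L, n_theta = 12L, n_z = 4L)
  f1 <- solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 1))
  f2 <- solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 2))
  expect_equal(f2$u, 2 * f1$u, tolerance = 1e-8)
  fr <- solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = -1))
  expect_equal(fr$u, -f1$u, tolerance = 1e-8)
})

test_that("moving-wall flux balances the swept volume within 0.5%", {
  tm <- tube_mesh(0.1, 0.5, n_r = 6L, n_theta = 16L, n_z = 6L)
  # radial wall expansion u_r = c at the wall
  c0 <- 0.01
  r <- sqrt(rowSums(tm$nodes[, 1:2, drop = FALSE]^2))
  uw <- matrix(0, nrow(tm$nodes), 3L)
  uw[tm$wall_nodes, 1] <- c0 * tm$nodes[tm$wall_nodes, 1] / r[tm$wall_nodes]
  uw[tm$wall_nodes, 2] <- c0 * tm$nodes[tm$wall_nodes, 2] / r[tm$wall_nodes]
  fl <- solve_low_re_flow(tm, uw, props19)
  # discrete swept rate = outward wall flux; open outflow must balance it
  swept <- fl$fluxes[["wall"]]
  expect_lt(abs(swept / (2 * pi * 0.1 * 0.5 * c0) - 1), 0.02)
  out <- fl$fluxes[["inlet"]] + fl$fluxes[["outlet"]]
  expect_lt(abs(out / (-swept) - 1), 0.005)
})

test_that("network flow obeys Ohm's-law and symmetry trivials", {
  # single edge to the atmosphere
  net <- duct_network(data.frame(from = 1L, to = 0L, g = 2.5), 1L)
  nf <- duct_network_flow(net, 0.05)
  expect_equal(nf$p[1], -0.05 / 2.5)
  # expansion draws air in: flux out of the acinus is -dV/dt
  expect_equal(nf$open_flux, -0.05, tolerance = 1e-12)
  # symmetric two-branch tree: equal flows, equal daughter pressures
  ed <- data.frame(from = c(1L, 1L, 2L, 3L), to = c(2L, 3L, 0L, 0L),
                   g = c(1, 1, 2, 2))
  net2 <- duct_network(ed, 3L)
  nf2 <- duct_network_flow(net2, c(0.04, 0, 0))
  expect_equal(nf2$edge_flow[1], nf2$edge_flow[2], tolerance = 1e-12)
  expect_equal(nf2$p[2], nf2$p[3], tolerance = 1e-12)
  expect_error(duct_network(data.frame(from = 1L, to = 0L, g = 1), 2L),
               class = "acinusim_invalid_parameter")
})

test_that("network resistance cross-validates against the 3D solve", {
  # gently tapered tube: series Poiseuille integral vs Stokes
  rfun <- function(z) 0.1 - 0.03 * z
  tm <- tube_mesh(0.1, 1, n_r = 8L, n_theta = 24L, n_z = 10L,
                  radius_profile = rfun)
  fl <- solve_low_re_flow(tm, 0, props19, open_pressure = c(inlet = 1))
  Rint <- stats::integrate(function(z) 8 * 1.9e-5 / (pi * rfun(z)^4), 0, 1,
                           rel.tol = 1e-10)$value
  expect_equal(unname(fl$fluxes[["outlet"]]), 1 / Rint, tolerance = 0.10)
})

test_that("acinus network conserves mass exactly and is connected", {
  g <- healthy_geometry()
  net <- acinus_network(g)
  set.seed(3)
  dv <- runif(nrow(g$cells), 0, 0.01)
  nf <- duct_network_flow(net, dv)
  expect_equal(nf$open_flux, -sum(dv), tolerance = 1e-12)
  # inflow lowers interior pressures below the open boundary
  expect_true(all(nf$p < 0))
})

test_that("Reynolds number arithmetic is dimensionally right", {
  expect_equal(reynolds_number(0), 0)
  # u = 1 mm/s, humid air at 37 C, L = 1 mm
  expect_equal(reynolds_number(1, 1), 1.145 * 1e-3 * 1e-3 / 1.86e-5,
               tolerance = 1e-12)
  expect_equal(reynolds_number(1, 1), 0.0616, tolerance = 0.01)
})
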