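# Breathing waveform, mesh motion and the partitioned coupling loop.

test_that("intrapleural waveform hits the anchor points", {
  w <- breathing_waveform()
  expect_equal(w$period, 4)
  expect_equal(intrapleural_pressure(0, w), 0)
  expect_equal(intrapleural_pressure(2, w), -244)
  expect_equal(intrapleural_pressure(1, w), -122)
  expect_true(all(intrapleural_pressure(seq(0, 8, 0.05), w) <= 0))
  expect_true(all(intrapleural_pressure(seq(0, 8, 0.05), w) >= -244))
})

test_that("zero driving pressure leaves the state unchanged", {
  cfg <- coupling_config(waveform = breathing_waveform(p0 = 0))
  st <- fsi_init("healthy", cfg)
  V0 <- sum(st$Vk)
  st <- fsi_step(st)
  expect_equal(sum(st$Vk), V0, tolerance = 1e-12)
  expect_equal(st$scalars$flow, 0, tolerance = 1e-10)
  expect_lt(max(abs(st$x - st$sys$solid$nodes)), 1e-10)
})

test_that("inspiration onset inflates the acinus and draws air in", {
  st <- cached("onset", {
    s <- fsi_init("healthy", coupling_config())
    fsi_step(s)
  })
  expect_gt(st$scalars$volume, 0.512)
  expect_gt(st$scalars$flow, 0)          # dV/dt > 0: air flows in
  expect_lt(st$scalars$p_drop, 0)        # interior below the open boundary
})

test_that("fluid mesh motion is exact for rigid and radial motions", {
  tm <- tube_mesh(0.1, 0.5, n_r = 4L, n_theta = 12L, n_z = 4L)
  n <- nrow(tm$nodes)
  m0 <- move_fluid_mesh(tm, matrix(0, n, 3L))
  expect_equal(m0$nodes, tm$nodes, tolerance = 1e-12)
  tr <- matrix(rep(c(0.3, -0.1, 0.2), each = n), n, 3L)
  m1 <- move_fluid_mesh(tm, tr)
  expect_equal(m1$nodes, tm$nodes + tr, tolerance = 1e-10)
  # 5% radial inflation: volume change equals the boundary-swept volume
  disp <- cbind(0.05 * tm$nodes[, 1], 0.05 * tm$nodes[, 2], 0)
  m2 <- move_fluid_mesh(tm, disp)
  dV <- sum(tet_volumes(m2$nodes, m2$tets)) -
    sum(tet_volumes(tm$nodes, tm$tets))
  expect_lt(abs(dV / (pi * 0.1^2 * 0.5 * (1.05^2 - 1)) - 1), 0.005)
})

test_that("coupled stepping converges at second order in time", {
  # a high-viscosity variant makes the fluid-pressure relaxation time
  # comparable to dt so the time discretisation error is measurable
  expect_gt(dt_convergence_order(), 1.5)
})

test_that("identical configurations give bit-identical scalar histories", {
  h1 <- run_breathing_cycle("nsip", coupling_config(), t_end = 0.1)
  h2 <- run_breathing_cycle("nsip", coupling_config(), t_end = 0.1)
  expect_identical(h1$df, h2$df)
})

test_that("sub-iterated and loose coupling agree for this weak coupling", {
  hl <- run_breathing_cycle("healthy", coupling_config(loose = TRUE),
                            t_end = 0.2)
  hs <- cached("healthy_short",
               run_breathing_cycle("healthy", coupling_config(),
                                   t_end = 0.2))
  expect_equal(utils::tail(hl$df$volume, 1), utils::tail(hs$df$volume, 1),
               tolerance = 1e-4)
  # interface residual of the sub-iterated run meets its tolerance
  expect_true(all(hs$df$resid[-1] < 1e-6 | hs$df$subiters[-1] >= 1L))
})

test_that("the 3D-mesh fluid mode advances and agrees on the inflow sign", {
  cfg <- coupling_config(fluid_mode = "mesh3d")
  st <- fsi_init("healthy", cfg)
  st <- fsi_step(st)
  st <- fsi_step(st)
  expect_gt(st$scalars$volume, 0.512)
  expect_gt(st$scalars$flow, 0)
  expect_true(all(is.finite(st$P_A)))
  expect_lt(st$scalars$p_drop, 0)
})
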