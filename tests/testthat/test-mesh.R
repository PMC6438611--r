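# Shell and tetrahedral mesh generation.

test_that("shell-mesh per-cell volumes close to the exact lumen volume", {
  g <- healthy_geometry()
  for (lev in 1:2) {
    sm <- build_shell_mesh(g, lev)
    cv <- cell_volumes(sm)
    expect_equal(sum(cv), lumen_volume(g), tolerance = 1e-10)
    expect_true(all(cv > 0))
  }
})

test_that("fluid tet meshes are valid with complete boundary labelling", {
  g <- healthy_geometry()
  ms <- generate_meshes(g, 1)
  ck <- check_mesh(ms$fluid)
  expect_true(ck$ok)
  expect_gt(ck$min_volume, 0)
  expect_equal(ck$n_unlabelled, 0L)
  expect_equal(sum(tet_volumes(ms$fluid$nodes, ms$fluid$tets)),
               lumen_volume(g), tolerance = 1e-10)
  # desk budget
  expect_lte(nrow(ms$fluid$tets), 5e4)
  expect_lte(nrow(ms$solid$tris), 3e4)
})

test_that("tube meshes preserve the circular cross-section area exactly", {
  tm <- tube_mesh(0.1, 1, n_r = 5L, n_theta = 16L, n_z = 6L)
  expect_equal(sum(tet_volumes(tm$nodes, tm$tets)), pi * 0.01,
               tolerance = 1e-12)
  expect_true(check_mesh(tm)$ok)
})

test_that("mesh volume converges monotonically under refinement", {
  # polygonal approximation error of the uncorrected circular tube shrinks
  # monotonically with azimuthal refinement
  errs <- vapply(c(8L, 16L, 32L), function(nt) {
    corr <- sqrt((2 * pi / nt) / sin(2 * pi / nt))
    tm <- tube_mesh(0.1, 1, n_r = 4L, n_theta = nt, n_z = 4L)
    v <- sum(tet_volumes(tm$nodes / c(corr, corr, 1), tm$tets))
    abs(v / (pi * 0.01) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("graded near-wall layers are generated when requested", {
  tm <- tube_mesh(0.1, 0.5, n_r = 6L, n_theta = 16L, n_z = 4L,
                  wall_layers = 2L)
  r <- sqrt(rowSums(tm$nodes[, 1:2, drop = FALSE]^2))
  rings <- sort(unique(round(r[abs(tm$nodes[, 3]) < 1e-12], 8)))
  gaps <- diff(tail(rings, 3L))
  expect_true(all(gaps < 0.6 * max(diff(rings))))
  expect_true(check_mesh(tm)$ok)
})

test_that("icosphere nodes lie on the sphere", {
  sp <- icosphere(0.5, 2)
  expect_equal(sqrt(rowSums(sp$nodes^2)), rep(0.5, nrow(sp$nodes)),
               tolerance = 1e-12)
})
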