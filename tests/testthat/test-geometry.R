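# Truncated-octahedron cells, acinus assembly and disease scenarios.

test_that("truncated octahedron has the exact closed-form volume and topology", {
  cell <- truncated_octahedron(1)
  expect_equal(polyhedron_volume(cell), 8 * sqrt(2), tolerance = 1e-10)
  expect_equal(length(cell$faces), 14L)
  expect_equal(sum(lengths(cell$faces) == 4L), 6L)
  expect_equal(sum(lengths(cell$faces) == 6L), 8L)
  # Euler characteristic V - E + F = 2
  edges <- unique(t(apply(do.call(rbind, lapply(cell$faces, function(f) {
    cbind(f, c(f[-1], f[1]))
  })), 1L, sort)))
  expect_equal(24L - nrow(edges) + 14L, 2L)
  # cubic scaling
  expect_equal(polyhedron_volume(truncated_octahedron(0.5)),
               8 * sqrt(2) * 0.125, tolerance = 1e-10)
  expect_error(truncated_octahedron(-1), class = "acinusim_invalid_parameter")
})

test_that("all volumes scale as the cube of the edge length", {
  g1 <- assemble_acinus(edge_length = 0.1)
  g2 <- assemble_acinus(edge_length = 0.2)
  expect_equal(lumen_volume(g2) / lumen_volume(g1), 8, tolerance = 1e-10)
  expect_equal(sum(g2$faces$area) / sum(g1$faces$area), 4, tolerance = 1e-10)
})

test_that("divergence-theorem lumen volume equals the summed cell volumes", {
  g <- assemble_acinus()
  expect_equal(lumen_volume(g), sum(g$cells$volume), tolerance = 1e-10)
})

test_that("assembled acinus volume agrees with a voxel-count oracle", {
  g <- assemble_acinus(edge_length = 0.12)
  s <- g$edge_length / sqrt(2)
  lay <- acinusim:::.acinus_sites()
  # point-in-cell: |x|,|y|,|z| <= 2s and |x|+|y|+|z| <= 3s about any center
  h <- s / 3
  lim <- apply(g$vertices, 2L, range)
  gx <- seq(lim[1, 1] + h / 2, lim[2, 1], by = h)
  gy <- seq(lim[1, 2] + h / 2, lim[2, 2], by = h)
  gz <- seq(lim[1, 3] + h / 2, lim[2, 3], by = h)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  inside <- rep(FALSE, nrow(pts))
  for (ci in seq_len(nrow(lay$sites))) {
    cen <- lay$sites[ci, ] * s
    d <- abs(sweep(pts[!inside, , drop = FALSE], 2L, cen))
    hit <- d[, 1] <= 2 * s & d[, 2] <= 2 * s & d[, 3] <= 2 * s &
      rowSums(d) <= 3 * s
    inside[!inside][hit] <- TRUE
  }
  v_vox <- sum(inside) * h^3
  expect_equal(v_vox, lumen_volume(g), tolerance = 0.02)
})

test_that("scenario presets carry the tabulated parameters", {
  p <- scenario_presets()
  expect_equal(p$healthy$E, 35714)
  expect_equal(p$healthy$primary_thickness, 0.025)
  expect_equal(p$healthy$target_resting_volume, 0.512)
  expect_equal(p$nsip$primary_thickness, p$nsip$secondary_thickness)
  expect_equal(p$nsip$primary_thickness, 0.050)
  expect_equal(p$nsip$target_resting_volume, 0.493)
  expect_equal(p$ipf$secondary_thickness, 0.025)
  expect_equal(p$ipf$target_resting_volume, 0.465)
  expect_equal(p$ipf$nu, 0.42)
})

test_that("scenario calibration reproduces the tabulated resting volumes", {
  g <- assemble_acinus()
  for (sc in c("healthy", "nsip", "ipf")) {
    gs <- apply_scenario(g, sc)
    expect_equal(lumen_volume(gs),
                 scenario_presets()[[sc]]$target_resting_volume,
                 tolerance = 0.01)
  }
  # applying the healthy scenario to the calibrated healthy geometry is a
  # no-op on the lumen shape
  gh <- apply_scenario(g, "healthy")
  gh2 <- apply_scenario(gh, "healthy")
  expect_equal(gh2$vertices, gh$vertices, tolerance = 1e-12)
})

test_that("pathological thickening that would seal an opening errors", {
  g <- assemble_acinus()
  bad <- disease_scenario("fibrotic_extreme", 0.4, 0.4, 35714, 0.42, 0.4)
  expect_error(apply_scenario(g, bad), class = "acinusim_geometry_error")
})

test_that("septal thickness map classifies every wall exactly once", {
  g <- apply_scenario(assemble_acinus(), "ipf")
  tm <- septal_thickness_map(g)
  expect_true(all(tm$class %in% c("primary", "secondary")))
  expect_true(all(tm$thickness > 0))
  expect_equal(sort(unique(tm$thickness[tm$class == "primary"])), 0.050)
  expect_equal(sort(unique(tm$thickness[tm$class == "secondary"])), 0.025)
  # tissue volume consistent with area x thickness
  expect_equal(tissue_volume(g),
               sum(g$faces$area[tm$face_id] * tm$thickness),
               tolerance = 1e-12)
})

test_that("degenerate topology (no alveoli) gives an exact cylinder", {
  topo <- acinus_topology(alveoli_per_sac = 0L)
  g <- assemble_acinus(topo)
  expect_equal(lumen_volume(g), pi * 0.137^2 * 1.0, tolerance = 1e-12)
})

test_that("scenario perturbation is deterministic and unbiased", {
  base <- scenario_presets()$healthy
  expect_identical(perturb_scenario(base, 0), base)
  a <- perturb_scenario(base, 0.1, seed = 42)
  b <- perturb_scenario(base, 0.1, seed = 42)
  expect_identical(a, b)
  # Monte-Carlo: mean of E across draws within 2 standard errors
  draws <- vapply(1:1000, function(s) perturb_scenario(base, 0.1, s)$E,
                  numeric(1))
  mu_ln <- base$E * exp(0.1^2 / 2)       # log-normal mean
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu_ln), 2 * se + 1e-9)
})
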