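# RBF interface transfer: reproduction and conservation properties.

test_that("transfer between identical meshes is the identity", {
  set.seed(11)
  pts <- matrix(runif(45), 15L, 3L)
  map <- build_interface_map(pts, pts)
  d <- matrix(rnorm(45), 15L, 3L)
  expect_equal(as.matrix(transfer_displacement(map, d)), d,
               tolerance = 1e-10)
})

test_that("constant and rigid-body fields are transferred exactly", {
  set.seed(12)
  src <- matrix(runif(60), 20L, 3L)
  tgt <- matrix(runif(36), 12L, 3L)
  map <- build_interface_map(src, tgt)
  dc <- matrix(rep(c(1, -2, 0.5), each = 20L), 20L, 3L)
  out <- as.matrix(transfer_displacement(map, dc))
  expect_equal(out, matrix(rep(c(1, -2, 0.5), each = 12L), 12L, 3L),
               tolerance = 1e-10)
})

test_that("linear fields are reproduced to 1e-10 on non-matching clouds", {
  set.seed(13)
  src <- matrix(runif(90), 30L, 3L)
  tgt <- matrix(runif(60), 20L, 3L)
  map <- build_interface_map(src, tgt)
  A <- matrix(rnorm(9), 3, 3); b <- rnorm(3)
  lin <- function(x) x %*% t(A) + matrix(b, nrow(x), 3, byrow = TRUE)
  expect_equal(as.matrix(transfer_displacement(map, lin(src))), lin(tgt),
               tolerance = 1e-10)
})

test_that("adjoint traction transfer conserves total force to 1e-10", {
  set.seed(14)
  src <- matrix(runif(75), 25L, 3L)
  tgt <- matrix(runif(54), 18L, 3L)
  map <- build_interface_map(src, tgt)
  f <- matrix(rnorm(54), 18L, 3L)
  fs <- as.matrix(transfer_traction(map, f))
  expect_equal(colSums(fs), colSums(f), tolerance = 1e-10)
})

test_that("degenerate point sets raise a conditioning error", {
  pts <- matrix(rep(c(0, 0, 0), each = 10L), 10L, 3L)  # all identical
  expect_error(build_interface_map(pts, pts),
               class = "acinusim_conditioning_error")
})
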