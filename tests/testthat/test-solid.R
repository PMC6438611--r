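# Neo-Hookean constitutive law and the quasi-static shell solver.

test_that("bulk and shear moduli follow the closed forms", {
  m <- moduli_from_E_nu(35714, 0.42)
  expect_equal(m$K, 35714 / (3 * (1 - 2 * 0.42)), tolerance = 1e-12)
  expect_equal(m$G, 35714 / (2 * (1 + 0.42)), tolerance = 1e-12)
  expect_equal(m$K, 74404.17, tolerance = 1e-6)
  expect_equal(m$G, 12575.35, tolerance = 1e-6)
  m2 <- moduli_from_E_nu(3, 0)
  expect_equal(m2$K, 1)
  expect_equal(m2$G, 1.5)
  # inverse identity 9KG/(3K+G) = E for random parameters
  set.seed(1)
  for (i in 1:5) {
    E <- runif(1, 1e3, 1e5); nu <- runif(1, 0.05, 0.45)
    m <- moduli_from_E_nu(E, nu)
    expect_equal(9 * m$K * m$G / (3 * m$K + m$G), E, tolerance = 1e-10)
  }
  expect_error(moduli_from_E_nu(1000, 0.5),
               class = "acinusim_incompressible_limit")
})

test_that("stored energy vanishes at identity and matches closed forms", {
  mat <- neo_hookean(35714, 0.42)
  expect_equal(strain_energy(diag(3), mat), 0)
  expect_equal(max(abs(cauchy_stress(diag(3), mat))), 0)
  # pure dilatation: isochoric term vanishes, W = K U(J)
  lam <- 1.1
  J <- lam^3
  W <- strain_energy(diag(lam, 3), mat)
  expect_equal(W, mat$K * 0.25 * (J^2 - 1 - 2 * log(J)), tolerance = 1e-12)
  # simple shear small-strain limit: W ~ G gamma^2 / 2
  gam <- 0.01
  F <- diag(3); F[1, 2] <- gam
  expect_equal(strain_energy(F, mat), mat$G * gam^2 / 2,
               tolerance = 1e-2)
  expect_error(strain_energy(diag(c(-1, 1, 1)), mat),
               class = "acinusim_inverted_element")
})

test_that("Cauchy stress equals the finite-difference energy gradient", {
  mat <- neo_hookean(35714, 0.42)
  set.seed(7)
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(F) <= 0.2) next
    # P = dW/dF by central differences; sigma = J^-1 P F'
    P <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(Fp, mat) - strain_energy(Fm, mat)) / (2 * h)
    }
    sig_fd <- P %*% t(F) / det(F)
    sig <- cauchy_stress(F, mat)
    expect_equal(sig, sig_fd, tolerance = 1e-6)
    expect_equal(sig, t(sig), tolerance = 1e-10)
  }
})

test_that("stored energy is objective under rotations", {
  mat <- neo_hookean(1e4, 0.3)
  set.seed(8)
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.1), 3, 3)
    if (det(F) <= 0.2) next
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                 3, 3, byrow = TRUE)
    Q <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
    expect_equal(strain_energy(Q %*% F, mat), strain_energy(F, mat),
                 tolerance = 1e-10)
  }
})

test_that("small-strain stress recovers linear elasticity", {
  mat <- neo_hookean(35714, 0.42)
  eps <- 1e-5
  # hydrostatic: tr(sigma)/3 = K tr(eps)
  sigh <- cauchy_stress(diag(1 + eps, 3), mat)
  expect_equal(sum(diag(sigh)) / 3, mat$K * 3 * eps, tolerance = 1e-3)
  # uniaxial stress state with lateral contraction nu: axial stress = E eps
  Fu <- diag(c(1 + eps, 1 - mat$nu * eps, 1 - mat$nu * eps))
  sigu <- cauchy_stress(Fu, mat)
  expect_equal(sigu[1, 1], mat$E * eps, tolerance = 1e-3)
  expect_lt(abs(sigu[2, 2]) / abs(sigu[1, 1]), 1e-2)
})

test_that("analytic hinge gradient matches finite differences", {
  set.seed(9)
  for (rep in 1:4) {
    nodes <- matrix(rnorm(12), 4, 3)
    tris <- if (rep %% 2 == 0) rbind(c(1, 2, 3), c(1, 2, 4)) else
      rbind(c(1, 2, 3), c(2, 1, 4))
    sm <- shell_from_surface(nodes, tris, 0.02)
    ga <- acinusim:::.hinge_grad(nodes, sm)
    gf <- acinusim:::.hinge_grad_fd(nodes, sm)
    for (k in 1:4) expect_equal(ga$grad[[k]], gf$grad[[k]], tolerance = 1e-5)
  }
})

test_that("zero load gives zero displacement", {
  sp <- icosphere(0.4, 2)
  sm <- shell_from_surface(sp$nodes, sp$tris, 0.02)
  st <- solve_quasistatic(sm, neo_hookean(1e4, 0.3),
                          bc = list(q = 0, spring = 1e-4))
  expect_lt(max(abs(st$u)), 1e-10)
})

test_that("pressurised thin sphere matches the Lame closed form", {
  mat <- neo_hookean(35714, 0.42)
  sp <- icosphere(0.5, 3)
  p <- 50   # keeps strains below 1%, inside the linear regime of the oracle
  sm <- shell_from_surface(sp$nodes, sp$tris, 0.025)
  st <- solve_quasistatic(sm, mat,
                          bc = list(q = rep(p, nrow(sm$tris)), spring = 1e-4))
  dR <- mean(sqrt(rowSums(st$x^2)) - 0.5)
  dR_exact <- p * 0.5^2 * (1 - 0.42) / (2 * 35714 * 0.025)
  expect_lt(abs(dR / dR_exact - 1), 0.05)
  # membrane stress ~ pR/2t
  mps <- max_principal_stress(st)
  expect_equal(mps$max, p * 0.5 / (2 * 0.025), tolerance = 0.1)
  # doubling the thickness halves the expansion
  sm2 <- shell_from_surface(sp$nodes, sp$tris, 0.050)
  st2 <- solve_quasistatic(sm2, mat,
                           bc = list(q = rep(p, nrow(sm2$tris)),
                                     spring = 1e-4))
  dR2 <- mean(sqrt(rowSums(st2$x^2)) - 0.5)
  expect_lt(abs(dR2 / dR / 0.5 - 1), 0.05)
})

test_that("principal stress of simple states is exact", {
  # a state whose Cauchy stress is uniaxial along x
  sig <- cbind(xx = 100, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0)
  st <- structure(list(sigma = sig,
                       mesh = list(tri_class = "primary")),
                  class = "deformation_state")
  mps <- max_principal_stress(st)
  expect_equal(unname(mps$max), 100)
  sig0 <- cbind(xx = 0, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0)
  st0 <- structure(list(sigma = sig0,
                        mesh = list(tri_class = "primary")),
                   class = "deformation_state")
  expect_equal(unname(max_principal_stress(st0)$max), 0)
})

test_that("small-strain shell response matches a linear elastic solve", {
  # at loads producing <1% strain the Neo-Hookean equilibrium is within 2%
  # of the linearised prediction u_lin = K0^-1 f
  g <- healthy_geometry()
  sm <- build_shell_mesh(g, 1)
  mat <- neo_hookean(35714, 0.42)
  pre <- acinusim:::.shell_precompute(sm, mat)
  q <- as.numeric(sm$tri_class == "primary") * 5   # 5 Pa inflation
  st <- solve_quasistatic(sm, mat, bc = list(q = q))
  K <- acinusim:::.assemble_tangent(sm$nodes, sm, pre, 0)
  n <- nrow(sm$nodes)
  fdof <- setdiff(seq_len(3 * n),
                  as.vector(rbind(3 * sm$fixed - 2, 3 * sm$fixed - 1,
                                  3 * sm$fixed)))
  gv <- acinusim:::.shell_grad(sm$nodes, sm, pre, q)
  ulin <- numeric(3 * n)
  ulin[fdof] <- -as.numeric(Matrix::solve(
    Matrix::forceSymmetric(K[fdof, fdof]),
    as.vector(t(gv$g))[fdof]))
  ulin <- matrix(ulin, n, 3, byrow = TRUE)
  expect_equal(max(abs(st$u - ulin)) / max(abs(ulin)), 0, tolerance = 0.02)
})
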