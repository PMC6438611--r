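# Quasi-static thin-shell solver for the septal tissue.
#
# Each wall triangle is a Neo-Hookean membrane in plane stress (the through-
# thickness stretch is condensed out element-wise from sigma_33 = 0), plus a
# discrete-shell hinge bending term with stiffness E t^3 / (12 (1 - nu^2))
# that supplies the transverse stiffness of the flat septal facets.  Pressure
# loads are follower loads (energy -q * enclosed volume per triangle).
# Equilibrium is found by Newton iteration with a cached sparse factorisation
# of an approximate tangent (linear membrane + geometric stress + bending),
# refreshed only when convergence degrades; inertia is dropped: at 0.25 Hz
# breathing the inertial stresses are many orders below the elastic ones.

#' Construct a shell solid from a bare triangle surface
#'
#' Convenience wrapper used for analytic verification cases (pressurised
#' sphere, plates): wraps `nodes`/`tris` into the same structure that
#' [build_shell_mesh()] produces for the acinus.
#'
#' @param nodes n x 3 node coordinates (mm).
#' @param tris m x 3 triangle node indices (consistently oriented).
#' @param thickness Wall thickness in mm (scalar or per-triangle).
#' @param fixed Integer vector of clamped node ids (default none).
#' @return A `shell_mesh`.
#' @export
shell_from_surface <- function(nodes, tris, thickness, fixed = integer(0)) {
  m <- nrow(tris)
  mesh <- structure(list(
    nodes = unname(as.matrix(nodes)), tris = unname(as.matrix(tris)),
    tri_face = seq_len(m), tri_class = rep("primary", m),
    tri_cell1 = rep(1L, m), tri_cell2 = rep(NA_integer_, m),
    tri_thickness = rep_len(thickness, m),
    cell_tris = data.frame(cell = rep(1L, m), tri = seq_len(m),
                           sign = rep(1, m)),
    cap_tris = matrix(0L, 0L, 3L), cap_cell = integer(0),
    cap_sign = numeric(0), fixed = fixed, n_cells = 1L, level = 1L,
    geom_scenario = NA_character_
  ), class = "shell_mesh")
  mesh$hinges <- .build_hinges(mesh)
  mesh
}

# ---- element precomputation ------------------------------------------------

.shell_precompute <- function(mesh, mat) {
  x <- mesh$nodes; tr <- mesh$tris
  e1 <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e2 <- x[tr[, 3], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  cr <- .vcross(e1, e2)
  a2 <- sqrt(rowSums(cr^2))
  A0 <- a2 / 2
  u1 <- e1 / sqrt(rowSums(e1^2))
  nrm <- cr / a2
  u2 <- .vcross(nrm, u1)
  d11 <- rowSums(e1 * u1)
  d12 <- rowSums(e2 * u1)
  d22 <- rowSums(e2 * u2)
  im11 <- 1 / d11
  im12 <- -d12 / (d11 * d22)
  im22 <- 1 / d22
  h <- mesh$hinges
  hx <- lapply(1:4, function(k) x[h[[k]], , drop = FALSE])
  th0 <- .hinge_theta(hx[[1]], hx[[2]], hx[[3]], hx[[4]], h$flip)
  tmean <- (mesh$tri_thickness[h$t1] + mesh$tri_thickness[h$t2]) / 2
  Dh <- mat$E * tmean^3 / (12 * (1 - mat$nu^2))
  elen2 <- rowSums((hx[[2]] - hx[[1]])^2)
  Ah <- A0[h$t1] + A0[h$t2]
  kh <- Dh * elen2 / (2 * Ah)
  vt_ref <- rowSums(x[tr[, 1], , drop = FALSE] *
                    .vcross(x[tr[, 2], , drop = FALSE],
                            x[tr[, 3], , drop = FALSE])) / 6
  list(A0 = A0, t0 = mesh$tri_thickness,
       im11 = im11, im12 = im12, im22 = im22,
       theta0 = th0, kh = kh, lam3 = rep(1, nrow(tr)), vt_ref = vt_ref,
       K = mat$K, G = mat$G, E = mat$E, nu = mat$nu)
}

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed dihedral deviation: 0 when the two flaps are coplanar
.hinge_theta <- function(p0, p1, p2, p3, flip = 1) {
  e <- p1 - p0
  n1 <- .vcross(e, p2 - p0)                 # normal of (p0, p1, p2)
  n2 <- .vcross(p0 - p1, p3 - p1)           # normal of (p1, p0, p3)
  n2 <- n2 * flip
  ehat <- e / sqrt(rowSums(e^2))
  atan2(rowSums(.vcross(n1, n2) * ehat), rowSums(n1 * n2))
}

# through-thickness stretch from plane stress: dW/dlam3 = 0, per element
.solve_lam3 <- function(c11, c12, c22, lam3, K, G, tol = 1e-12, maxit = 50L) {
  d <- c11 * c22 - c12^2
  A <- sqrt(pmax(d, 1e-300))
  I2 <- c11 + c22
  for (it in seq_len(maxit)) {
    J <- lam3 * A
    Jm23 <- J^(-2 / 3)
    g <- K / 2 * (J - 1 / J) * A +
      G * (-(1 / 3) * Jm23 / J * A * (I2 + lam3^2) + Jm23 * lam3)
    gp <- K / 2 * (1 + 1 / J^2) * A^2 +
      G * ((5 / 9) * Jm23 / J^2 * A^2 * (I2 + lam3^2) -
           2 * Jm23 / J * A * lam3 + Jm23)
    step <- g / gp
    lam3n <- lam3 - step
    lam3 <- ifelse(lam3n > 0.2 * lam3, lam3n, 0.2 * lam3)
    if (max(abs(step)) < tol) break
  }
  lam3
}

# membrane energy + gradient contributions; returns list(W, h1, h2) where
# h1/h2 are dE/dx1, dE/dx2 (dE/dx0 = -h1-h2), plus stress info
.membrane_eval <- function(x, mesh, pre, want_stress = FALSE) {
  tr <- mesh$tris
  e1 <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e2 <- x[tr[, 3], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  f1 <- e1 * pre$im11
  f2 <- e1 * pre$im12 + e2 * pre$im22
  c11 <- rowSums(f1 * f1)
  c12 <- rowSums(f1 * f2)
  c22 <- rowSums(f2 * f2)
  lam3 <- .solve_lam3(c11, c12, c22, pre$lam3, pre$K, pre$G)
  pre$lam3 <- lam3
  d <- c11 * c22 - c12^2
  A <- sqrt(pmax(d, 1e-300))
  J <- lam3 * A
  IC <- c11 + c22 + lam3^2
  Jm23 <- J^(-2 / 3)
  W <- pre$K / 4 * (J^2 - 1 - 2 * log(J)) + pre$G / 2 * (Jm23 * IC - 3)
  # S = 2 dW/dC (2x2, at stationary lam3)
  ci11 <- c22 / d; ci22 <- c11 / d; ci12 <- -c12 / d
  co <- pre$K / 2 * (J^2 - 1) - pre$G * Jm23 * IC / 3
  s11 <- co * ci11 + pre$G * Jm23
  s22 <- co * ci22 + pre$G * Jm23
  s12 <- co * ci12
  w <- pre$A0 * pre$t0
  p1 <- f1 * s11 + f2 * s12
  p2 <- f1 * s12 + f2 * s22
  h1 <- (p1 * pre$im11 + p2 * pre$im12) * w
  h2 <- (p2 * pre$im22) * w
  out <- list(E = sum(w * W), h1 = h1, h2 = h2, lam3 = lam3)
  if (want_stress) {
    # in-plane Cauchy stress sigma = J^-1 F S F' (rank-2, 3x3)
    q1 <- (f1 * s11 + f2 * s12) / J
    q2 <- (f1 * s12 + f2 * s22) / J
    sig <- cbind(
      q1[, 1] * f1[, 1] + q2[, 1] * f2[, 1],                          # xx
      q1[, 2] * f1[, 2] + q2[, 2] * f2[, 2],                          # yy
      q1[, 3] * f1[, 3] + q2[, 3] * f2[, 3],                          # zz
      q1[, 1] * f1[, 2] + q2[, 1] * f2[, 2],                          # xy
      q1[, 1] * f1[, 3] + q2[, 1] * f2[, 3],                          # xz
      q1[, 2] * f1[, 3] + q2[, 2] * f2[, 3]                           # yz
    )
    colnames(sig) <- c("xx", "yy", "zz", "xy", "xz", "yz")
    out$sigma <- sig
    out$S <- cbind(s11 = s11, s12 = s12, s22 = s22)
  }
  out
}

# analytic dihedral-angle gradient (12 dofs per hinge), vectorised
.hinge_grad <- function(x, mesh) {
  h <- mesh$hinges
  p0 <- x[h$n0, , drop = FALSE]; p1 <- x[h$n1, , drop = FALSE]
  p2 <- x[h$n2, , drop = FALSE]; p3 <- x[h$n3, , drop = FALSE]
  e <- p1 - p0
  elen <- sqrt(rowSums(e^2))
  n1 <- .vcross(e, p2 - p0)
  n2r <- .vcross(p0 - p1, p3 - p1)
  n2 <- n2r * h$flip
  n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
  g2 <- -n1 * (elen / n1sq)
  g3 <- -n2r * (elen / n2sq)           # x3 rotates the physical flap 2
  a0 <- rowSums((p2 - p1) * e) / (elen * n1sq)
  b0 <- rowSums((p3 - p1) * e) / (elen * n2sq)
  a1 <- rowSums((p2 - p0) * e) / (elen * n1sq)
  b1 <- rowSums((p3 - p0) * e) / (elen * n2sq)
  g0 <- -(n1 * a0 + n2r * b0)
  g1 <- n1 * a1 + n2r * b1
  list(theta = .hinge_theta(p0, p1, p2, p3, h$flip),
       grad = list(g0, g1, g2, g3))
}

# finite-difference hinge-angle gradient (test oracle for .hinge_grad)
.hinge_grad_fd <- function(x, mesh) {
  h <- mesh$hinges
  p <- lapply(1:4, function(k) x[h[[k]], , drop = FALSE])
  step <- 1e-6 * sqrt(rowSums((p[[2]] - p[[1]])^2))
  g <- vector("list", 4L)
  for (k in 1:4) {
    gk <- matrix(0, nrow(h), 3L)
    for (c_ in 1:3) {
      pp <- p; pm <- p
      pp[[k]][, c_] <- pp[[k]][, c_] + step
      pm[[k]][, c_] <- pm[[k]][, c_] - step
      gk[, c_] <- (.hinge_theta(pp[[1]], pp[[2]], pp[[3]], pp[[4]], h$flip) -
                   .hinge_theta(pm[[1]], pm[[2]], pm[[3]], pm[[4]], h$flip)) /
        (2 * step)
    }
    g[[k]] <- gk
  }
  list(theta = .hinge_theta(p[[1]], p[[2]], p[[3]], p[[4]], h$flip), grad = g)
}

# total energy and gradient; q = per-triangle follower traction (Pa, along
# the triangle normal given by vertex order)
.shell_grad <- function(x, mesh, pre, q) {
  mem <- .membrane_eval(x, mesh, pre)
  pre$lam3 <- mem$lam3
  n <- nrow(x)
  tr <- mesh$tris
  contrib <- rbind(-mem$h1 - mem$h2, mem$h1, mem$h2)
  ids <- c(tr[, 1], tr[, 2], tr[, 3])
  E <- mem$E
  # bending
  if (nrow(mesh$hinges) > 0L) {
    hg <- .hinge_grad(x, mesh)
    dth <- hg$theta - pre$theta0
    E <- E + sum(pre$kh * dth^2)
    coef <- 2 * pre$kh * dth
    for (k in 1:4) {
      contrib <- rbind(contrib, hg$grad[[k]] * coef)
      ids <- c(ids, mesh$hinges[[k]])
    }
  }
  # follower pressure: E_p = -sum q * V_tri
  x0 <- x[tr[, 1], , drop = FALSE]
  x1 <- x[tr[, 2], , drop = FALSE]
  x2 <- x[tr[, 3], , drop = FALSE]
  vt <- rowSums(x0 * .vcross(x1, x2)) / 6
  E <- E - sum(q * (vt - pre$vt_ref))
  fq <- q / 6
  g0 <- -fq * .vcross(x1, x2)
  g1 <- -fq * .vcross(x2, x0)
  g2 <- -fq * .vcross(x0, x1)
  contrib <- rbind(contrib, g0, g1, g2)
  ids <- c(ids, tr[, 1], tr[, 2], tr[, 3])
  gsum <- rowsum(contrib, group = ids)
  g <- matrix(0, n, 3L)
  g[as.integer(rownames(gsum)), ] <- gsum
  fext <- sqrt(sum(rbind(g0, g1, g2)^2))
  list(E = E, g = g, fext = fext, lam3 = mem$lam3)
}

# energy only (for line search)
.shell_energy <- function(x, mesh, pre, q) {
  mem <- .membrane_eval(x, mesh, pre)
  E <- mem$E
  if (nrow(mesh$hinges) > 0L) {
    h <- mesh$hinges
    th <- .hinge_theta(x[h$n0, , drop = FALSE], x[h$n1, , drop = FALSE],
                       x[h$n2, , drop = FALSE], x[h$n3, , drop = FALSE],
                       h$flip)
    E <- E + sum(pre$kh * (th - pre$theta0)^2)
  }
  tr <- mesh$tris
  vt <- rowSums(x[tr[, 1], , drop = FALSE] *
                .vcross(x[tr[, 2], , drop = FALSE],
                        x[tr[, 3], , drop = FALSE])) / 6
  E - sum(q * (vt - pre$vt_ref))
}

# ---- approximate tangent assembly -----------------------------------------

# linear CST membrane + geometric stress + bending Gauss-Newton (+ springs),
# fully vectorised over elements
.assemble_tangent <- function(x, mesh, pre, spring = 0) {
  tr <- mesh$tris
  m <- nrow(tr); n <- nrow(x)
  e1 <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e2 <- x[tr[, 3], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  cr <- .vcross(e1, e2)
  a2 <- sqrt(rowSums(cr^2)); A <- a2 / 2
  u1 <- e1 / sqrt(rowSums(e1^2))
  nrm <- cr / a2
  u2 <- .vcross(nrm, u1)
  x1l <- rowSums(e1 * u1); x2l <- rowSums(e2 * u1); y2l <- rowSums(e2 * u2)
  # CST shape-function gradients in the local frame
  twoA <- 2 * A
  bb <- cbind(-y2l, y2l, 0) / twoA
  cc <- cbind(x2l - x1l, -x2l, x1l) / twoA
  D11 <- pre$E / (1 - pre$nu^2); D12 <- pre$nu * D11
  D33 <- pre$E / (2 * (1 + pre$nu))
  At <- A * pre$t0
  mem <- .membrane_eval(x, mesh, pre, want_stress = TRUE)
  S <- mem$S
  # Gm = L %*% Dm^-1 rows (per element)
  g1x <- -pre$im11; g1y <- -pre$im12 - pre$im22
  g2x <- pre$im11;  g2y <- pre$im12
  g3x <- rep(0, m); g3y <- pre$im22
  Gx <- cbind(g1x, g2x, g3x); Gy <- cbind(g1y, g2y, g3y)
  nent <- 81L * m
  ii <- integer(nent); jj <- integer(nent); vv <- numeric(nent)
  pos <- 0L
  w0 <- pre$A0 * pre$t0
  for (a_ in 1:3) for (b_ in 1:3) {
    k11 <- At * (D11 * bb[, a_] * bb[, b_] + D33 * cc[, a_] * cc[, b_])
    k12 <- At * (D12 * bb[, a_] * cc[, b_] + D33 * cc[, a_] * bb[, b_])
    k21 <- At * (D12 * cc[, a_] * bb[, b_] + D33 * bb[, a_] * cc[, b_])
    k22 <- At * (D11 * cc[, a_] * cc[, b_] + D33 * bb[, a_] * bb[, b_])
    kg <- w0 * (Gx[, a_] * (S[, "s11"] * Gx[, b_] + S[, "s12"] * Gy[, b_]) +
                Gy[, a_] * (S[, "s12"] * Gx[, b_] + S[, "s22"] * Gy[, b_]))
    na_ <- tr[, a_]; nb_ <- tr[, b_]
    for (i in 1:3) for (j in 1:3) {
      val <- k11 * u1[, i] * u1[, j] + k12 * u1[, i] * u2[, j] +
             k21 * u2[, i] * u1[, j] + k22 * u2[, i] * u2[, j]
      if (i == j) val <- val + kg
      ii[pos + seq_len(m)] <- 3L * na_ - 3L + i
      jj[pos + seq_len(m)] <- 3L * nb_ - 3L + j
      vv[pos + seq_len(m)] <- val
      pos <- pos + m
    }
  }
  # bending Gauss-Newton
  nh <- nrow(mesh$hinges)
  if (nh > 0L) {
    hg <- .hinge_grad(x, mesh)
    h <- mesh$hinges
    gmat <- cbind(hg$grad[[1]], hg$grad[[2]], hg$grad[[3]], hg$grad[[4]])
    nds <- cbind(h$n0, h$n1, h$n2, h$n3)
    dofm <- matrix(0L, nh, 12L)
    for (k in 1:4) {
      dofm[, 3L * k - 2L] <- 3L * nds[, k] - 2L
      dofm[, 3L * k - 1L] <- 3L * nds[, k] - 1L
      dofm[, 3L * k] <- 3L * nds[, k]
    }
    iib <- integer(144L * nh); jjb <- integer(144L * nh)
    vvb <- numeric(144L * nh)
    posb <- 0L
    coefb <- 2 * pre$kh
    for (a_ in 1:12) for (b_ in 1:12) {
      iib[posb + seq_len(nh)] <- dofm[, a_]
      jjb[posb + seq_len(nh)] <- dofm[, b_]
      vvb[posb + seq_len(nh)] <- coefb * gmat[, a_] * gmat[, b_]
      posb <- posb + nh
    }
    ii <- c(ii, iib); jj <- c(jj, jjb); vv <- c(vv, vvb)
  }
  K <- sparseMatrix(i = ii, j = jj, x = vv, dims = c(3L * n, 3L * n))
  if (spring > 0) K <- K + Diagonal(3L * n, spring)
  K
}

# ---- quasi-static solve ----------------------------------------------------

#' Quasi-static equilibrium of the Neo-Hookean shell
#'
#' Newton iteration on the total-energy gradient (elastic + bending -
#' follower pressure work) with a cached approximate tangent; converges to a
#' relative residual below `control$tol` or raises a diagnostic error
#' carrying the last residual.  Load sub-stepping is applied automatically on
#' divergence.
#'
#' @param mesh A `shell_mesh`.
#' @param mat A [neo_hookean()] material.
#' @param bc List: `q` per-triangle normal traction (Pa, positive along the
#'   triangle normal), `fixed` extra clamped node ids (merged with
#'   `mesh$fixed`), `spring` optional weak tether stiffness (Pa mm, per dof)
#'   used to remove rigid modes on closed surfaces.
#' @param prior Optional previous `deformation_state` used as the predictor.
#' @param control List: `tol` (relative residual, default 1e-8), `maxit`,
#'   `cache` (environment reusing the factorised tangent across calls).
#' @return Object of class `deformation_state`: node positions `x`,
#'   displacement `u`, per-element Cauchy stress, `residual`, `iterations`.
#' @export
solve_quasistatic <- function(mesh, mat, bc, prior = NULL, control = list()) {
  ctl <- modifyList(list(tol = 1e-8, maxit = 200L, cache = NULL,
                         fscale_min = 0, refresh = FALSE, depth = 0L),
                    control)
  q <- bc$q %||% numeric(nrow(mesh$tris))
  q <- rep_len(q, nrow(mesh$tris))
  fixed <- sort(unique(c(mesh$fixed, bc$fixed)))
  spring <- bc$spring %||% 0
  cache <- ctl$cache %||% new.env(parent = emptyenv())
  if (is.null(cache$pre)) cache$pre <- .shell_precompute(mesh, mat)
  pre <- cache$pre
  n <- nrow(mesh$nodes)
  fdof <- setdiff(seq_len(3L * n),
                  as.vector(rbind(3L * fixed - 2L, 3L * fixed - 1L, 3L * fixed)))
  x <- if (!is.null(prior)) prior$x else mesh$nodes

  refactor <- function(xc) {
    K <- .assemble_tangent(xc, mesh, pre, spring = spring)
    Kff <- forceSymmetric(K[fdof, fdof])
    # keep the preconditioner positive definite (compressive membrane stress
    # can make the geometric part indefinite): escalate a diagonal shift
    shift <- 0
    dmax <- max(abs(Matrix::diag(Kff)))
    repeat {
      f <- tryCatch(
        Cholesky(Kff + Diagonal(length(fdof), shift), LDL = FALSE,
                 perm = TRUE),
        error = function(e) NULL)
      if (!is.null(f)) break
      shift <- if (shift == 0) 1e-8 * dmax else shift * 100
      if (shift > dmax) {
        stop_acinusim("tangent stiffness could not be regularised",
                      "acinusim_newton_failure")
      }
    }
    cache$fact <- f
  }
  if (is.null(cache$fact) || isTRUE(ctl$refresh)) refactor(x)
  else if ((cache$iters_last %||% 0L) > 25L) refactor(x)
  ksolve <- function(rhs) as.numeric(Matrix::solve(cache$fact, rhs))

  gv <- .shell_grad(x, mesh, pre, q)
  # intrinsic elastic force scale keeps the relative criterion meaningful
  # for (near-)zero external load
  f_char <- 1e-6 * sqrt(sum((pre$E * pre$t0)^2 * pre$A0))
  fscale <- max(gv$fext, ctl$fscale_min, f_char, spring * 1e-3, 1e-12)
  n_refresh <- 0L
  converged <- FALSE
  it <- 0L
  while (it < ctl$maxit) {
    it <- it + 1L
    gfree <- as.vector(t(gv$g))[fdof]
    res <- sqrt(sum(gfree^2)) / fscale
    if (res < ctl$tol) { converged <- TRUE; break }
    dx <- numeric(3L * n)
    dx[fdof] <- -ksolve(gfree)
    step <- matrix(dx, n, 3L, byrow = TRUE)
    alpha <- 1
    E0 <- gv$E
    slope <- sum(gfree * dx[fdof])
    if (res < 1e-3 ||
        abs(slope) < 1e3 * .Machine$double.eps * max(abs(E0), 1e-6)) {
      # near the solution the energy decrease drowns in summation roundoff;
      # Newton is locally convergent, so take the undamped step (divergence
      # is caught by the residual safeguard below)
      xn <- x + step
      ok <- TRUE
    } else {
      ok <- FALSE
      for (ls in 1:25) {
        xn <- x + alpha * step
        En <- .shell_energy(xn, mesh, pre, q)
        if (is.finite(En) && En <= E0 + 1e-4 * alpha * slope) { ok <- TRUE; break }
        alpha <- alpha / 2
      }
    }
    if (!ok) {
      if (n_refresh < 5L) { refactor(x); n_refresh <- n_refresh + 1L; next }
      break
    }
    gv_new <- .shell_grad(xn, mesh, pre, q)
    res_new <- sqrt(sum(as.vector(t(gv_new$g))[fdof]^2)) / fscale
    if (res_new > 10 * res && res_new > 100 * ctl$tol) {
      # undamped step diverged: refresh the tangent and retry from x
      if (n_refresh < 5L) { refactor(x); n_refresh <- n_refresh + 1L; next }
      break
    }
    x <- xn
    gv <- gv_new
    # stale tangent slows convergence at geometrically stiffened states:
    # reassemble with the current stress every 10 iterations
    if (it %% 10L == 0L && n_refresh < 5L) {
      refactor(x)
      n_refresh <- n_refresh + 1L
    }
  }
  cache$iters_last <- it
  if (!converged) {
    # load sub-stepping
    if (ctl$depth < 5L && sqrt(sum(q^2)) > 0) {
      half <- bc; half$q <- q / 2
      st_half <- solve_quasistatic(mesh, mat, half, prior = prior,
                                   control = modifyList(ctl, list(depth = ctl$depth + 1L, cache = cache)))
      return(solve_quasistatic(mesh, mat, bc, prior = st_half,
                               control = modifyList(ctl, list(depth = ctl$depth + 1L, cache = cache))))
    }
    gfree <- as.vector(t(gv$g))[fdof]
    stop_acinusim(sprintf(
      "quasi-static solve did not converge: residual %.3e after %d iterations",
      sqrt(sum(gfree^2)) / fscale, it),
      "acinusim_newton_failure", residual = sqrt(sum(gfree^2)) / fscale)
  }
  mem <- .membrane_eval(x, mesh, pre, want_stress = TRUE)
  pre$lam3 <- mem$lam3
  gfree <- as.vector(t(gv$g))[fdof]
  structure(list(
    x = x, u = x - mesh$nodes, sigma = mem$sigma, lam3 = mem$lam3,
    energy = gv$E, residual = sqrt(sum(gfree^2)) / fscale,
    iterations = it, converged = TRUE, mesh = mesh, q = q
  ), class = "deformation_state")
}

#' Maximum principal Cauchy stress per shell element
#'
#' Largest eigenvalue of the (rank-two, in-plane) Cauchy stress of each wall
#' triangle, with per-class summaries for primary and secondary septa.
#'
#' @param state A `deformation_state` from [solve_quasistatic()].
#' @return List: `per_element` (Pa), `max`, and `by_class` named maxima.
#' @export
max_principal_stress <- function(state) {
  sg <- state$sigma
  tr_ <- sg[, "xx"] + sg[, "yy"] + sg[, "zz"]
  q <- sg[, "xx"]^2 + sg[, "yy"]^2 + sg[, "zz"]^2 +
    2 * (sg[, "xy"]^2 + sg[, "xz"]^2 + sg[, "yz"]^2)
  disc <- pmax(q / 2 - tr_^2 / 4, 0)
  smax <- tr_ / 2 + sqrt(disc)
  cls <- state$mesh$tri_class
  by_class <- tapply(smax, cls, max)
  list(per_element = smax, max = max(smax), by_class = by_class)
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf(
    "<deformation_state: %d nodes, max |u| = %.4g mm, residual %.2e (%d it)>\n",
    nrow(x$x), max(sqrt(rowSums(x$u^2))), x$residual, x$iterations))
  invisible(x)
}
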