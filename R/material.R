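# Neo-Hookean constitutive model for the septal tissue.
#
# Stored energy (modified Neo-Hookean):
#   W = K U(J) + G/2 (J^(-2/3) I_C - 3),   U(J) = 1/4 (J^2 - 1 - 2 ln J)
# with J = det F, I_C = tr(F'F), parameterized by the equivalent small-strain
# modulus E and Poisson ratio nu through K = E/(3(1-2nu)), G = E/(2(1+nu)).

#' Bulk and shear moduli from (E, nu)
#'
#' @param E Equivalent small-strain modulus (Pa), > 0.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return Named list with `K` (bulk, Pa) and `G` (shear, Pa).
#' @examples
#' moduli_from_E_nu(35714, 0.42)
#' @export
moduli_from_E_nu <- function(E, nu) {
  if (E <= 0) stop_acinusim("E must be positive", "acinusim_invalid_parameter")
  if (nu >= 0.5) {
    stop_acinusim("nu must be below the incompressible limit 0.5",
                  "acinusim_incompressible_limit")
  }
  if (nu < 0) stop_acinusim("nu must be non-negative",
                            "acinusim_invalid_parameter")
  list(K = E / (3 * (1 - 2 * nu)), G = E / (2 * (1 + nu)))
}

#' Neo-Hookean material
#'
#' @inheritParams moduli_from_E_nu
#' @return Object of class `neo_hookean` with fields `E`, `nu`, `K`, `G`.
#' @export
neo_hookean <- function(E, nu) {
  m <- moduli_from_E_nu(E, nu)
  structure(list(E = E, nu = nu, K = m$K, G = m$G), class = "neo_hookean")
}

#' Neo-Hookean stored energy density
#'
#' @param F Deformation gradient, 3 x 3 matrix with `det F > 0`.
#' @param mat A [neo_hookean()] material.
#' @return Energy density W in Pa; zero at `F = diag(3)`.
#' @export
strain_energy <- function(F, mat) {
  J <- det(F)
  if (J <= 0) {
    stop_acinusim("det F must be positive (inverted element)",
                  "acinusim_inverted_element")
  }
  IC <- sum(F * F)
  mat$K * 0.25 * (J^2 - 1 - 2 * log(J)) +
    mat$G / 2 * (J^(-2 / 3) * IC - 3)
}

#' Cauchy stress of the Neo-Hookean model
#'
#' `sigma = J^-1 (dW/dF) F' = K/2 (J - 1/J) I + G J^(-5/3) dev(B)` with
#' `B = F F'`; symmetric, zero at identity, and consistent with linear
#' elasticity (`sigma ~ K tr(eps) I + 2 G dev(eps)`) at small strain.
#'
#' @inheritParams strain_energy
#' @return 3 x 3 symmetric Cauchy stress (Pa).
#' @export
cauchy_stress <- function(F, mat) {
  J <- det(F)
  if (J <= 0) {
    stop_acinusim("det F must be positive (inverted element)",
                  "acinusim_inverted_element")
  }
  B <- F %*% t(F)
  IC <- sum(diag(B))
  mat$K / 2 * (J - 1 / J) * diag(3) +
    mat$G * J^(-5 / 3) * (B - IC / 3 * diag(3))
}

#' @export
print.neo_hookean <- function(x, ...) {
  cat(sprintf("<neo_hookean: E=%.6g Pa nu=%.3g (K=%.6g, G=%.6g Pa)>\n",
              x$E, x$nu, x$K, x$G))
  invisible(x)
}
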