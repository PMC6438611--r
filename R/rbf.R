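# Radial-basis-function transfer between non-matching interface meshes.
#
# Wendland C2 kernel with linear polynomial augmentation: interpolation of
# displacements from the solid interface points to the fluid boundary points,
# and the transposed (conservative) operator for tractions/forces in the
# opposite direction.  Linear fields are reproduced exactly, and the adjoint
# transfer conserves the total interface force component-wise.

.wendland_c2 <- function(r, rho) {
  x <- pmin(r / rho, 1)
  (1 - x)^4 * (4 * x + 1)
}

#' Build an RBF interface transfer map
#'
#' @param source_points n_s x 3 matrix (solid interface nodes).
#' @param target_points n_t x 3 matrix (fluid interface nodes).
#' @param support Kernel support radius in mm; default twice the source
#'   cloud's bounding-box diagonal (global support).
#' @param regularization Ridge term added to the kernel block for
#'   conditioning (default 1e-12 of the diagonal scale).
#' @return Object of class `interface_map` carrying the dense n_t x n_s
#'   transfer matrix `H` (rows sum to 1).
#' @export
build_interface_map <- function(source_points, target_points,
                                support = NULL, regularization = 1e-12) {
  S <- as.matrix(source_points); Tt <- as.matrix(target_points)
  ns <- nrow(S)
  if (ns < 4L) {
    stop_acinusim("need at least 4 source points", "acinusim_invalid_parameter")
  }
  if (is.null(support)) {
    support <- 2 * sqrt(sum((apply(S, 2L, max) - apply(S, 2L, min))^2))
  }
  d2 <- function(A, B) {
    outer(rowSums(A^2), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  }
  Phi <- .wendland_c2(sqrt(pmax(d2(S, S), 0)), support)
  P <- cbind(1, S)
  if (qr(P)$rank < 4L) {
    stop_acinusim("degenerate point set: source points are coplanar or coincident",
                  "acinusim_conditioning_error")
  }
  M <- rbind(cbind(Phi + regularization * diag(ns), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  # conditioning guard
  ev <- tryCatch(solve(M, diag(nrow(M))), error = function(e)
    stop_acinusim("degenerate point set: RBF system is singular",
                  "acinusim_conditioning_error"))
  Phi_t <- .wendland_c2(sqrt(pmax(d2(Tt, S), 0)), support)
  H <- cbind(Phi_t, 1, Tt) %*% ev[, seq_len(ns), drop = FALSE]
  structure(list(H = H, source = S, target = Tt, support = support),
            class = "interface_map")
}

#' Transfer a displacement field from source to target points
#'
#' @param map An [build_interface_map()] map.
#' @param d n_s x k displacement (or any nodal field) at the source points.
#' @return n_t x k interpolated field at the target points.
#' @export
transfer_displacement <- function(map, d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == nrow(map$source))
  map$H %*% d
}

#' Transfer nodal forces from target to source points (conservative adjoint)
#'
#' Uses the transpose of the displacement operator so that the virtual work
#' and the total force are identical on both sides.
#'
#' @param map An [build_interface_map()] map.
#' @param f n_t x k nodal forces at the target (fluid) points.
#' @return n_s x k nodal forces at the source (solid) points.
#' @export
transfer_traction <- function(map, f) {
  f <- as.matrix(f)
  stopifnot(nrow(f) == nrow(map$target))
  t(map$H) %*% f
}
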