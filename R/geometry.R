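# Polyhedral acinus geometry: truncated-octahedron cells on a BCC lattice,
# assembled into a two-generation alveolar duct with 14-hedron alveoli.
#
# Lattice convention: cell centers and all cell vertices live on the integer
# lattice in units of s = edge_length / sqrt(2).  A truncated octahedron
# centered at integer point c has vertices c + perm(0, +-1, +-2), so shared
# faces of neighbouring cells match exactly by integer vertex keys.

#' Truncated octahedron (14-hedron) cell
#'
#' Builds the 24-vertex, 14-face truncated octahedron used as the idealised
#' alveolus: 6 square and 8 hexagonal faces, space-filling on a BCC lattice.
#'
#' @param edge_length Edge length in mm (> 0); all 36 edges are equal.
#' @param center Numeric length-3 center (mm).
#' @return Object of class `polyhedral_cell` with fields `vertices` (24 x 3,
#'   mm), `faces` (list of vertex-index vectors, ordered counter-clockwise
#'   seen from outside), `edge_length`, `center`.
#' @examples
#' cell <- truncated_octahedron(1)
#' polyhedron_volume(cell) # 8 * sqrt(2)
#' @export
truncated_octahedron <- function(edge_length, center = c(0, 0, 0)) {
  if (!is.numeric(edge_length) || length(edge_length) != 1L ||
      !is.finite(edge_length) || edge_length <= 0) {
    stop_acinusim("edge_length must be a single positive number",
                  "acinusim_invalid_parameter")
  }
  stopifnot(length(center) == 3L)
  s <- edge_length / sqrt(2)
  vi <- .to_vertices_int()                       # 24 x 3 integers
  faces <- .to_faces_int(vi)
  structure(list(
    vertices = sweep(vi * s, 2L, as.numeric(center), "+"),
    faces = faces,
    edge_length = edge_length,
    center = as.numeric(center)
  ), class = "polyhedral_cell")
}

# integer vertices of the reference TO: all permutations of (0, +-1, +-2)
.to_vertices_int <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- matrix(0L, 0L, 3L)
  base <- c(0L, 1L, 2L)
  for (p in perms) {
    for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) {
      v <- base[order(p)]
      v <- base
      # place (0,1,2) into slots given by permutation p, then apply signs
      w <- integer(3L); w[p] <- base
      w[w == 1L] <- s1; w[w == 2L] <- 2L * s2
      out <- rbind(out, w)
    }
  }
  out <- unique(out)
  stopifnot(nrow(out) == 24L)
  dimnames(out) <- NULL
  out
}

# faces of the reference TO as ordered vertex-index lists (outward CCW)
.to_faces_int <- function(vi) {
  faces <- list()
  # 6 squares: vertices with coordinate k equal to +-2
  for (k in 1:3) for (sg in c(2L, -2L)) {
    idx <- which(vi[, k] == sg)
    faces[[length(faces) + 1L]] <- .order_face(vi, idx, center = c(0, 0, 0))
  }
  # 8 hexagons: vertices with v . sigma == 3
  for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) for (s3 in c(1L, -1L)) {
    idx <- which(vi[, 1] * s1 + vi[, 2] * s2 + vi[, 3] * s3 == 3L)
    faces[[length(faces) + 1L]] <- .order_face(vi, idx, center = c(0, 0, 0))
  }
  faces
}

# order face vertices CCW about the outward normal (away from cell center)
.order_face <- function(verts, idx, center) {
  pts <- verts[idx, , drop = FALSE]
  fc <- colMeans(pts)
  nrm <- fc - center
  nrm <- nrm / sqrt(sum(nrm^2))
  # in-plane frame
  ref <- pts[1, ] - fc
  ref <- ref - sum(ref * nrm) * nrm
  ref <- ref / sqrt(sum(ref^2))
  ref2 <- c(nrm[2] * ref[3] - nrm[3] * ref[2],
            nrm[3] * ref[1] - nrm[1] * ref[3],
            nrm[1] * ref[2] - nrm[2] * ref[1])
  rel <- sweep(pts, 2L, fc)
  ang <- atan2(rel %*% ref2, rel %*% ref)
  idx[order(ang)]
}

#' Signed volume of a closed polyhedral surface
#'
#' Divergence-theorem volume of a `polyhedral_cell`, positive for outward
#' oriented faces.
#' @param cell A `polyhedral_cell`.
#' @return Volume in mm^3.
#' @export
polyhedron_volume <- function(cell) {
  v <- 0
  for (f in cell$faces) {
    pts <- cell$vertices[f, , drop = FALSE]
    fc <- colMeans(pts)
    nf <- length(f)
    for (i in seq_len(nf)) {
      j <- if (i == nf) 1L else i + 1L
      v <- v + .tet_vol6(fc, pts[i, ], pts[j, ])
    }
  }
  v / 6
}

.tet_vol6 <- function(a, b, c) {
  a[1] * (b[2] * c[3] - b[3] * c[2]) +
  a[2] * (b[3] * c[1] - b[1] * c[3]) +
  a[3] * (b[1] * c[2] - b[2] * c[1])
}

#' Acinus topology parameters
#'
#' Two generations of alveolar ducts feeding two blind-ended alveolar sacs of
#' 12 truncated-octahedron alveoli each.  Only the tabulated configuration
#' (2 generations, 12 alveoli per sac) or the degenerate straight-tube case
#' (0 alveoli) are supported.
#'
#' @param generations Number of duct generations (fixed at 2).
#' @param alveoli_per_sac Alveoli per sac: 12, or 0 for a plain duct tube.
#' @param duct_diameter Characteristic duct diameter in mm.
#' @param sac_length Nominal alveolar-sac length in mm.
#' @return Object of class `acinus_topology`.
#' @export
acinus_topology <- function(generations = 2L, alveoli_per_sac = 12L,
                            duct_diameter = 0.274, sac_length = 1.0) {
  if (!alveoli_per_sac %in% c(0L, 12L)) {
    stop_acinusim("alveoli_per_sac must be 12 (or 0 for a plain tube)",
                  "acinusim_invalid_parameter")
  }
  if (generations != 2L) {
    stop_acinusim("only two duct generations are supported",
                  "acinusim_invalid_parameter")
  }
  structure(list(generations = 2L,
                 alveoli_per_sac = as.integer(alveoli_per_sac),
                 duct_diameter = duct_diameter,
                 sac_length = sac_length),
            class = "acinus_topology")
}

# Occupied lattice sites of the acinus (integer centers, units of s):
# a two-cell parent duct along z, bifurcating into two sacs, each a
# three-cell duct column surrounded by 12 alveoli in three columns of four.
.acinus_sites <- function() {
  sac <- function(sgn) {
    duct <- cbind(2L * sgn, 2L * sgn, c(2L, 6L, 10L))
    cols <- rbind(c(0L, 4L), c(4L, 0L), c(4L, 4L)) * sgn
    alv <- do.call(rbind, lapply(c(0L, 4L, 8L, 12L), function(z)
      cbind(cols, z)))
    list(duct = duct, alveoli = alv)
  }
  A <- sac(1L); B <- sac(-1L)
  parent <- rbind(c(0L, 0L, 0L), c(0L, 0L, -4L))
  sites <- rbind(parent, A$duct, B$duct, A$alveoli, B$alveoli)
  type <- c(rep("parent", 2L), rep("duct", 6L), rep("alveolus", 24L))
  list(sites = sites, type = type,
       open_cell = 2L,                    # distal parent cell
       open_normal = c(0L, 0L, -1L))      # its -z square face is the mouth
}

#' Assemble the two-generation acinus geometry
#'
#' Packs truncated-octahedron cells on a BCC lattice into a parent duct, a
#' symmetric bifurcation and two alveolar sacs of 12 alveoli each; faces on
#' the duct path and between ducts and alveoli are removed to form the duct
#' lumen and the alveolar mouths, leaving a single open (inlet/outlet) square
#' face on the proximal parent duct.  Interior alveolus-alveolus walls are
#' classified as secondary septa; walls facing the exterior are primary septa.
#'
#' With `alveoli_per_sac = 0` the geometry degenerates to a straight
#' cylindrical duct of the topology's diameter (useful as an analytic
#' reference).
#'
#' @param topology An [acinus_topology()].
#' @param edge_length Truncated-octahedron edge length in mm (the build
#'   scale; disease calibration rescales it, see [apply_scenario()]).
#' @return Object of class `acinus_geometry`: `vertices` (mm), `faces`
#'   (data frame: class, cells, area, thickness), `face_verts` (ordered
#'   vertex indices, oriented out of `cell1`), `cells` (data frame),
#'   plus topology, edge length and calibration scale.
#' @export
assemble_acinus <- function(topology = acinus_topology(), edge_length = 0.12) {
  if (edge_length <= 0) {
    stop_acinusim("edge_length must be positive", "acinusim_invalid_parameter")
  }
  if (topology$alveoli_per_sac == 0L) {
    return(.tube_geometry(topology, edge_length))
  }
  s <- edge_length / sqrt(2)
  lay <- .acinus_sites()
  sites <- lay$sites
  ncell <- nrow(sites)
  site_key <- apply(sites, 1L, paste, collapse = "_")

  vi_ref <- .to_vertices_int()
  faces_ref <- .to_faces_int(vi_ref)

  vkey_map <- new.env(hash = TRUE, parent = emptyenv())
  verts_int <- matrix(0L, 0L, 3L)
  nvert <- 0L
  get_vert <- function(v) {
    key <- paste(v, collapse = "_")
    id <- vkey_map[[key]]
    if (is.null(id)) {
      nvert <<- nvert + 1L
      verts_int <<- rbind(verts_int, v)
      vkey_map[[key]] <- nvert
      id <- nvert
    }
    id
  }

  face_map <- new.env(hash = TRUE, parent = emptyenv())
  face_verts <- list()
  face_cell1 <- integer(); face_cell2 <- integer()
  nface <- 0L

  for (ci in seq_len(ncell)) {
    cen <- sites[ci, ]
    for (f in faces_ref) {
      fv_int <- sweep(vi_ref[f, , drop = FALSE], 2L, cen, "+")
      ids <- apply(fv_int, 1L, get_vert)
      fkey <- paste(sort(ids), collapse = "_")
      fid <- face_map[[fkey]]
      if (is.null(fid)) {
        nface <- nface + 1L
        face_map[[fkey]] <- nface
        face_verts[[nface]] <- ids        # oriented out of first owner
        face_cell1[nface] <- ci
        face_cell2[nface] <- NA_integer_
      } else {
        face_cell2[[fid]] <- ci
      }
    }
  }

  type <- lay$type
  is_duct <- function(i) type[i] %in% c("parent", "duct")
  cls <- character(nface)
  for (fi in seq_len(nface)) {
    c1 <- face_cell1[fi]; c2 <- face_cell2[fi]
    if (is.na(c2)) {
      cls[fi] <- "primary"
    } else if (is_duct(c1) && is_duct(c2)) {
      cls[fi] <- "duct"
    } else if (is_duct(c1) || is_duct(c2)) {
      cls[fi] <- "mouth"
    } else {
      cls[fi] <- "secondary"
    }
  }
  # the open boundary: -z square face of the distal parent cell
  open_cen <- sites[lay$open_cell, ] + lay$open_normal * 2L
  for (fi in seq_len(nface)) {
    if (cls[fi] == "primary" && face_cell1[fi] == lay$open_cell) {
      fc <- colMeans(verts_int[face_verts[[fi]], , drop = FALSE])
      if (all(abs(fc - open_cen) < 0.5)) cls[fi] <- "open"
    }
  }

  verts <- verts_int * s
  geom <- structure(list(
    unit = "mm",
    topology = topology,
    edge_length = edge_length,
    scale = 1.0,
    scenario = NULL,
    vertices = verts,
    verts_int = verts_int,
    face_verts = face_verts,
    faces = data.frame(
      id = seq_len(nface), class = cls,
      cell1 = face_cell1, cell2 = face_cell2,
      thickness = NA_real_, area = NA_real_
    ),
    cells = data.frame(
      id = seq_len(ncell), type = type,
      cx = sites[, 1] * s, cy = sites[, 2] * s, cz = sites[, 3] * s,
      volume = rep(8 * sqrt(2) * edge_length^3, ncell)
    ),
    kind = "acinus"
  ), class = "acinus_geometry")
  geom$faces$area <- .face_areas(geom)
  # healthy septal thicknesses as a neutral default until a scenario is applied
  geom$faces$thickness <- 0.025
  geom
}

# degenerate geometry: a straight open cylinder (duct only, no alveoli)
.tube_geometry <- function(topology, edge_length) {
  structure(list(
    unit = "mm", topology = topology, edge_length = edge_length,
    scale = 1.0, scenario = NULL, kind = "tube",
    radius = topology$duct_diameter / 2,
    length = topology$sac_length
  ), class = "acinus_geometry")
}

.face_areas <- function(geom) {
  vapply(geom$face_verts, function(ids) {
    pts <- geom$vertices[ids, , drop = FALSE]
    fc <- colMeans(pts)
    a <- 0
    n <- nrow(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      e1 <- pts[i, ] - fc; e2 <- pts[j, ] - fc
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      a <- a + sqrt(sum(cr^2)) / 2
    }
    a
  }, numeric(1))
}

#' Lumen volume of an acinus geometry
#'
#' Divergence-theorem volume over the lumen boundary (primary septa plus the
#' open face treated as a cap).  For the lattice geometry this equals the sum
#' of the occupied cell volumes to round-off.
#'
#' @param geom An `acinus_geometry`.
#' @return Volume in mm^3 (positive).
#' @export
lumen_volume <- function(geom) {
  stopifnot(inherits(geom, "acinus_geometry"))
  if (geom$kind == "tube") {
    return(pi * geom$radius^2 * geom$length)
  }
  keep <- geom$faces$class %in% c("primary", "open")
  v <- 0
  for (fi in geom$faces$id[keep]) {
    ids <- geom$face_verts[[fi]]
    pts <- geom$vertices[ids, , drop = FALSE]
    fc <- colMeans(pts)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      v <- v + .tet_vol6(fc, pts[i, ], pts[j, ])
    }
  }
  v <- v / 6
  if (v <= 0) {
    stop_acinusim("non-watertight or inverted lumen surface",
                  "acinusim_geometry_error")
  }
  v
}

#' Tissue volume of the septal walls
#'
#' Thin-shell tissue volume: sum over kept septa of face area times local
#' thickness.
#' @param geom An `acinus_geometry` with an applied scenario (thickness map).
#' @return Volume in mm^3.
#' @export
tissue_volume <- function(geom) {
  stopifnot(inherits(geom, "acinus_geometry"), geom$kind == "acinus")
  keep <- geom$faces$class %in% c("primary", "secondary")
  sum(geom$faces$area[keep] * geom$faces$thickness[keep])
}

#' Septal thickness map
#'
#' @param geom An `acinus_geometry`.
#' @return Data frame with `face_id`, `class` (primary/secondary) and
#'   `thickness` (mm) for every wall face.
#' @export
septal_thickness_map <- function(geom) {
  stopifnot(inherits(geom, "acinus_geometry"), geom$kind == "acinus")
  keep <- geom$faces$class %in% c("primary", "secondary")
  data.frame(face_id = geom$faces$id[keep],
             class = geom$faces$class[keep],
             thickness = geom$faces$thickness[keep])
}

#' Apply a disease scenario to the healthy reference geometry
#'
#' Septal fibrosis is modelled as interstitial (outward) wall thickening: the
#' lumen surface shape is preserved, the per-class wall thickness is set from
#' the scenario, and a global isotropic scale factor calibrates the resting
#' lumen volume to the scenario target.  Openings (duct path, alveolar
#' mouths) therefore narrow with the global scale, and their orifice channels
#' lengthen with the septal thickness, which is how disease raises airway
#' resistance here.
#'
#' @param geom The healthy reference `acinus_geometry` from
#'   [assemble_acinus()].
#' @param scenario A [disease_scenario()].
#' @return Calibrated `acinus_geometry` with thickness map and scenario
#'   attached; resting lumen volume equals the scenario target (when given)
#'   to round-off.
#' @export
apply_scenario <- function(geom, scenario) {
  stopifnot(inherits(geom, "acinus_geometry"))
  scenario <- as_disease_scenario(scenario)
  if (!is.null(geom$scenario) && !identical(geom$scenario$name, "healthy")) {
    stop_acinusim("scenario must be applied to the healthy reference geometry",
                  "acinusim_geometry_error")
  }
  if (geom$kind == "tube") {
    geom$scenario <- scenario
    return(geom)
  }
  thick <- ifelse(geom$faces$class == "primary",
                  scenario$primary_thickness,
                  scenario$secondary_thickness)
  # opening closure guard: a wall thicker than an opening's diameter seals it
  open_cls <- geom$faces$class %in% c("mouth", "duct", "open")
  r_eq <- sqrt(geom$faces$area[open_cls] / pi)
  t_open <- ifelse(geom$faces$class[open_cls] == "open",
                   scenario$primary_thickness, scenario$secondary_thickness)
  if (any(t_open / 2 >= r_eq)) {
    stop_acinusim("septal thickening closes a duct or mouth lumen",
                  "acinusim_geometry_error")
  }
  v_built <- sum(geom$cells$volume)
  lambda <- if (is.finite(scenario$target_resting_volume %||% NA_real_)) {
    (scenario$target_resting_volume / v_built)^(1 / 3)
  } else 1.0
  geom$vertices <- geom$vertices * lambda
  geom$edge_length <- geom$edge_length * lambda
  geom$scale <- geom$scale * lambda
  geom$cells$volume <- geom$cells$volume * lambda^3
  geom$cells$cx <- geom$cells$cx * lambda
  geom$cells$cy <- geom$cells$cy * lambda
  geom$cells$cz <- geom$cells$cz * lambda
  geom$faces$area <- geom$faces$area * lambda^2
  geom$faces$thickness <- thick
  geom$scenario <- scenario
  geom
}

#' @export
print.acinus_geometry <- function(x, ...) {
  if (x$kind == "tube") {
    cat(sprintf("<acinus_geometry: straight duct tube R=%.4g mm L=%.4g mm>\n",
                x$radius, x$length))
    return(invisible(x))
  }
  cat(sprintf(
    "<acinus_geometry: %d cells (%d alveoli), %d faces, lumen %.4g mm^3%s>\n",
    nrow(x$cells), sum(x$cells$type == "alveolus"), nrow(x$faces),
    sum(x$cells$volume),
    if (is.null(x$scenario)) "" else paste0(", scenario ", x$scenario$name)))
  invisible(x)
}
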