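# Surface (shell) and volume (tetrahedral) mesh generation.
#
# The solid is discretised as a thin shell on the septal mid-surfaces
# (triangles with per-face thickness); the fluid lumen as tetrahedra obtained
# by coning each polyhedral cell's triangulated faces to the cell center.
# Meshes are conforming across cells because shared faces are triangulated
# once from a global registry.

# ---- generic triangle-surface helpers --------------------------------------

# subdivide every triangle into four; returns new nodes/tris, a row map
# (old tri -> 4 new tris in order), and the edge-midpoint lookup
.subdivide_tris <- function(nodes, tris) {
  n0 <- nrow(nodes)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  keys <- ek(e_all[, 1], e_all[, 2])
  uk <- unique(keys)
  mid_id <- setNames(seq_along(uk) + n0, uk)
  ue <- e_all[!duplicated(keys), , drop = FALSE]
  mid_nodes <- (nodes[ue[, 1], , drop = FALSE] + nodes[ue[, 2], , drop = FALSE]) / 2
  m12 <- mid_id[ek(tris[, 1], tris[, 2])]
  m23 <- mid_id[ek(tris[, 2], tris[, 3])]
  m31 <- mid_id[ek(tris[, 3], tris[, 1])]
  newtris <- rbind(
    cbind(tris[, 1], m12, m31),
    cbind(m12, tris[, 2], m23),
    cbind(m31, m23, tris[, 3]),
    cbind(m12, m23, m31)
  )
  nt <- nrow(tris)
  ord <- as.vector(t(matrix(seq_len(4L * nt), nt, 4L)))  # group by parent
  newtris <- newtris[ord, , drop = FALSE]
  parent <- rep(seq_len(nt), each = 4L)
  list(nodes = rbind(nodes, mid_nodes), tris = unname(newtris),
       parent = parent, mid_id = mid_id)
}

# insert subdivision midpoints into a closed node cycle; rim edges bordered
# only by removed faces have no midpoint node and keep their endpoints
.refine_cycle <- function(cycle, mid_id) {
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  nxt <- c(cycle[-1], cycle[1])
  mids <- unname(mid_id[ek(cycle, nxt)])
  out <- integer(0)
  for (i in seq_along(cycle)) {
    out <- c(out, cycle[i])
    if (!is.na(mids[i])) out <- c(out, mids[i])
  }
  out
}

.tri_areas <- function(nodes, tris) {
  e1 <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  e2 <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# signed tetrahedron volumes (rows of `tets` index `nodes`)
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
   b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# ---- shell (solid) mesh ----------------------------------------------------

#' Build the thin-shell solid mesh of the septal walls
#'
#' Triangulates every kept septal face (fan about its centroid) and carries
#' per-triangle thickness and wall class; records, per polyhedral cell, the
#' oriented wall triangles and opening cap fans needed to evaluate per-cell
#' lumen volumes from displaced nodes; and marks the open-boundary rim ring
#' as the fixed (clamped) node set.
#'
#' @param geom An `acinus_geometry` with scenario applied.
#' @param level Refinement level (1 = one fan per face; each extra level
#'   quadrisects every triangle).
#' @return Object of class `shell_mesh`.
#' @export
build_shell_mesh <- function(geom, level = 1L) {
  stopifnot(inherits(geom, "acinus_geometry"), geom$kind == "acinus")
  if (is.null(geom$scenario)) {
    stop_acinusim("apply a scenario before meshing (thickness map needed)",
                  "acinusim_geometry_error")
  }
  level <- max(1L, min(as.integer(level), 3L))
  keep <- which(geom$faces$class %in% c("primary", "secondary"))
  removed <- which(geom$faces$class %in% c("mouth", "duct", "open"))

  nodes <- geom$vertices
  nv <- nrow(nodes)
  tris <- matrix(0L, 0L, 3L)
  tri_face <- integer(0)
  for (fi in keep) {
    ids <- geom$face_verts[[fi]]
    cen <- colMeans(geom$vertices[ids, , drop = FALSE])
    nodes <- rbind(nodes, cen)
    cid <- nrow(nodes)
    k <- length(ids)
    f_t <- cbind(rep(cid, k), ids, c(ids[-1], ids[1]))
    tris <- rbind(tris, f_t)
    tri_face <- c(tri_face, rep(fi, k))
  }
  # opening cap cycles (oriented out of cell1 of the face)
  cap_cycles <- lapply(removed, function(fi) geom$face_verts[[fi]])
  names(cap_cycles) <- as.character(removed)

  lev <- 1L
  while (lev < level) {
    sub <- .subdivide_tris(nodes, tris)
    nodes <- sub$nodes
    tris <- sub$tris
    tri_face <- tri_face[sub$parent]
    cap_cycles <- lapply(cap_cycles, .refine_cycle, mid_id = sub$mid_id)
    lev <- lev + 1L
  }

  fclass <- geom$faces$class
  tri_class <- fclass[tri_face]
  tri_cell1 <- geom$faces$cell1[tri_face]
  tri_cell2 <- geom$faces$cell2[tri_face]
  tri_thick <- geom$faces$thickness[tri_face]

  # per-cell oriented wall triangles
  ct_cell <- c(tri_cell1, tri_cell2)
  ct_tri <- c(seq_len(nrow(tris)), seq_len(nrow(tris)))
  ct_sign <- c(rep(1, nrow(tris)), rep(-1, nrow(tris)))
  ok <- !is.na(ct_cell)
  cell_tris <- data.frame(cell = ct_cell[ok], tri = ct_tri[ok],
                          sign = ct_sign[ok])

  # cap fans: triangles (r1, ri, ri+1) per opening, signed per adjacent cell
  cap_tris <- matrix(0L, 0L, 3L); cap_cell <- integer(0); cap_sign <- numeric(0)
  for (nm in names(cap_cycles)) {
    fi <- as.integer(nm)
    cyc <- cap_cycles[[nm]]
    k <- length(cyc)
    fan <- cbind(rep(cyc[1], k - 2L), cyc[2:(k - 1L)], cyc[3:k])
    for (side in 1:2) {
      cell <- if (side == 1) geom$faces$cell1[fi] else geom$faces$cell2[fi]
      if (is.na(cell)) next
      cap_tris <- rbind(cap_tris, fan)
      cap_cell <- c(cap_cell, rep(cell, nrow(fan)))
      cap_sign <- c(cap_sign, rep(if (side == 1) 1 else -1, nrow(fan)))
    }
  }

  open_fi <- which(geom$faces$class == "open")
  fixed <- unique(cap_cycles[[as.character(open_fi)]])

  mesh <- structure(list(
    nodes = unname(nodes), tris = unname(tris),
    tri_face = tri_face, tri_class = tri_class,
    tri_cell1 = tri_cell1, tri_cell2 = tri_cell2,
    tri_thickness = tri_thick,
    cell_tris = cell_tris,
    cap_tris = unname(cap_tris), cap_cell = cap_cell, cap_sign = cap_sign,
    fixed = fixed,
    n_cells = nrow(geom$cells),
    level = level, geom_scenario = geom$scenario$name
  ), class = "shell_mesh")
  mesh$hinges <- .build_hinges(mesh)
  mesh
}

# hinge list for bending: edges shared by exactly two wall triangles.
# `flip` is -1 when the second triangle traverses the edge in the same
# direction as the first (locally inconsistent orientation), so that the
# dihedral angle is measured consistently and is 0 for coplanar flaps.
.build_hinges <- function(mesh) {
  tris <- mesh$tris
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e_all <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  opp <- c(tris[, 3], tris[, 1], tris[, 2])
  tid <- rep(seq_len(nrow(tris)), 3L)
  keys <- ek(e_all[, 1], e_all[, 2])
  tab <- table(keys)
  shared <- names(tab)[tab == 2L]
  idx <- split(seq_along(keys), keys)[shared]
  i1 <- vapply(idx, `[`, integer(1), 1L)
  i2 <- vapply(idx, `[`, integer(1), 2L)
  flip <- ifelse(e_all[i2, 1] == e_all[i1, 1], -1, 1)
  data.frame(
    n0 = e_all[i1, 1], n1 = e_all[i1, 2],
    n2 = opp[i1], n3 = opp[i2],
    t1 = tid[i1], t2 = tid[i2], flip = flip
  )
}

#' Per-cell lumen volumes from (displaced) shell nodes
#'
#' Closes each polyhedral cell with its wall triangles plus cap fans over the
#' openings and evaluates the divergence-theorem volume.  Summed over cells,
#' interior caps cancel so the total equals the whole-lumen volume.
#'
#' @param mesh A [build_shell_mesh()] mesh.
#' @param x Node positions (defaults to the reference nodes).
#' @return Numeric vector of cell volumes (mm^3).
#' @export
cell_volumes <- function(mesh, x = mesh$nodes) {
  tv <- function(tris) {
    a <- x[tris[, 1], , drop = FALSE]
    b <- x[tris[, 2], , drop = FALSE]
    c_ <- x[tris[, 3], , drop = FALSE]
    (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
     a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
     a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  }
  wall_v <- tv(mesh$tris)
  v <- rowsum(wall_v[mesh$cell_tris$tri] * mesh$cell_tris$sign,
              group = mesh$cell_tris$cell)
  out <- numeric(mesh$n_cells)
  out[as.integer(rownames(v))] <- v
  cap_v <- tv(mesh$cap_tris) * mesh$cap_sign
  vc <- rowsum(cap_v, group = mesh$cap_cell)
  out[as.integer(rownames(vc))] <- out[as.integer(rownames(vc))] + vc
  out
}

# ---- fluid (tetrahedral) meshes -------------------------------------------

#' Build the tetrahedral fluid mesh of the lumen
#'
#' Triangulates every face (kept and removed) from the shared registry,
#' optionally quadrisected `level - 1` times, and cones each cell's face
#' triangles to the cell center.  Boundary facets on primary septa are
#' labelled `wall`, the open face `open`; interior septa are internal no-slip
#' surfaces (their nodes are listed in `wall_nodes`).
#'
#' @param geom An `acinus_geometry` (scenario applied).
#' @param level Refinement level (1-3).
#' @return Object of class `fluid_mesh` with `nodes`, `tets`, boundary facet
#'   data frame `patches` (`n1,n2,n3,label`), `wall_nodes`, `open_nodes`.
#' @export
build_fluid_mesh <- function(geom, level = 1L) {
  stopifnot(inherits(geom, "acinus_geometry"), geom$kind == "acinus")
  level <- max(1L, min(as.integer(level), 3L))
  nodes <- geom$vertices
  tris <- matrix(0L, 0L, 3L)
  tri_face <- integer(0)
  nf <- nrow(geom$faces)
  for (fi in seq_len(nf)) {
    ids <- geom$face_verts[[fi]]
    cen <- colMeans(geom$vertices[ids, , drop = FALSE])
    nodes <- rbind(nodes, cen)
    cid <- nrow(nodes)
    k <- length(ids)
    tris <- rbind(tris, cbind(rep(cid, k), ids, c(ids[-1], ids[1])))
    tri_face <- c(tri_face, rep(fi, k))
  }
  lev <- 1L
  while (lev < level) {
    sub <- .subdivide_tris(nodes, tris)
    nodes <- sub$nodes; tris <- sub$tris
    tri_face <- tri_face[sub$parent]
    lev <- lev + 1L
  }
  ncell <- nrow(geom$cells)
  centers <- as.matrix(geom$cells[, c("cx", "cy", "cz")])
  nodes <- rbind(nodes, centers)
  center_id <- nrow(nodes) - ncell + seq_len(ncell)

  fcls <- geom$faces$class
  c1 <- geom$faces$cell1[tri_face]
  c2 <- geom$faces$cell2[tri_face]
  # cone to cell1 (reverse orientation so the tet is positive) and to cell2
  t1 <- cbind(tris[, 1], tris[, 3], tris[, 2], center_id[c1])
  has2 <- !is.na(c2)
  t2 <- cbind(tris[has2, 1], tris[has2, 2], tris[has2, 3],
              center_id[c2[has2]])
  tets <- rbind(t1, t2)
  tet_cell <- c(c1, c2[has2])
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  cls_tri <- fcls[tri_face]
  bnd <- cls_tri %in% c("primary", "open")
  patches <- data.frame(
    n1 = tris[bnd, 1], n2 = tris[bnd, 2], n3 = tris[bnd, 3],
    label = ifelse(cls_tri[bnd] == "open", "open", "wall")
  )
  wall_tris <- tris[cls_tri %in% c("primary", "secondary"), , drop = FALSE]
  wall_nodes <- sort(unique(as.vector(wall_tris)))
  open_nodes <- setdiff(sort(unique(as.vector(
    tris[cls_tri == "open", , drop = FALSE]))), wall_nodes)

  structure(list(
    nodes = unname(nodes), tets = unname(tets), tet_cell = tet_cell,
    patches = patches, wall_nodes = wall_nodes, open_nodes = open_nodes,
    level = level
  ), class = "fluid_mesh")
}

#' Structured tetrahedral mesh of a straight or tapered circular tube
#'
#' Tensor-product disc-times-axis mesh split into tetrahedra via wedge
#' centroids (conforming by the lowest-global-index diagonal rule).  Ring
#' nodes are placed slightly outside the nominal radius so the polygonal
#' cross-section preserves the circular area exactly; with `wall_layers > 0`
#' the outermost rings are compressed into thin graded near-wall layers.
#'
#' @param radius Tube radius in mm, or the radius at `z = 0` when
#'   `radius_profile` is given.
#' @param length Tube length (mm); axis along +z from 0.
#' @param n_r,n_theta,n_z Radial, azimuthal and axial divisions.
#' @param radius_profile Optional function `r(z)` for a tapered tube.
#' @param wall_layers Number of thin graded near-wall rings (0 or 2).
#' @return A `fluid_mesh` with patches `wall`, `inlet` (z = 0) and `outlet`.
#' @export
tube_mesh <- function(radius, length, n_r = 8L, n_theta = 24L, n_z = 10L,
                      radius_profile = NULL, wall_layers = 0L) {
  stopifnot(radius > 0, length > 0, n_r >= 2L, n_theta >= 8L, n_z >= 2L)
  corr <- sqrt((2 * pi / n_theta) / sin(2 * pi / n_theta))
  rr <- seq_len(n_r) / n_r
  if (wall_layers >= 2L) {
    inner <- seq_len(n_r - 2L) / (n_r - 2L) * 0.9
    rr <- c(inner, 0.96, 1.0)
  }
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  zz <- seq(0, length, length.out = n_z + 1L)
  rfun <- if (is.null(radius_profile)) function(z) radius else radius_profile

  n_slice <- 1L + n_r * n_theta
  id <- function(iz, ir, it) {
    # ir = 0 -> center
    off <- (iz - 1L) * n_slice
    if (ir == 0L) off + 1L else off + 1L + (ir - 1L) * n_theta +
      ((it - 1L) %% n_theta) + 1L
  }
  nodes <- matrix(0, (n_z + 1L) * n_slice, 3L)
  for (iz in seq_len(n_z + 1L)) {
    Rz <- rfun(zz[iz]) * corr
    nodes[id(iz, 0L, 1L), ] <- c(0, 0, zz[iz])
    for (ir in seq_len(n_r)) for (it in seq_len(n_theta)) {
      nodes[id(iz, ir, it), ] <-
        c(Rz * rr[ir] * cos(th[it]), Rz * rr[ir] * sin(th[it]), zz[iz])
    }
  }
  # slice triangles
  tri <- matrix(0L, 0L, 3L)
  for (it in seq_len(n_theta)) {
    tri <- rbind(tri, c(1L, 1L + it, 1L + (it %% n_theta) + 1L))
  }
  ring_id <- function(ir, it) 1L + (ir - 1L) * n_theta + ((it - 1L) %% n_theta) + 1L
  for (ir in seq_len(n_r - 1L)) for (it in seq_len(n_theta)) {
    a <- ring_id(ir, it); b <- ring_id(ir, it + 1L)
    A <- ring_id(ir + 1L, it); B <- ring_id(ir + 1L, it + 1L)
    tri <- rbind(tri, c(a, A, B), c(a, B, b))
  }
  ntri <- nrow(tri)

  # wedges -> 8 tets via centroid; quad diagonals by lowest global index
  tets <- matrix(0L, 0L, 4L)
  extra <- matrix(0, 0L, 3L)
  nbase <- nrow(nodes)
  for (iz in seq_len(n_z)) {
    lo <- (iz - 1L) * n_slice
    hi <- iz * n_slice
    for (k in seq_len(ntri)) {
      a <- tri[k, 1] + lo; b <- tri[k, 2] + lo; c_ <- tri[k, 3] + lo
      A <- tri[k, 1] + hi; B <- tri[k, 2] + hi; C <- tri[k, 3] + hi
      cen <- colMeans(nodes[c(a, b, c_, A, B, C), ])
      extra <- rbind(extra, cen)
      m <- nbase + nrow(extra)
      quad_t <- function(p, q, P, Q) {
        # face p-q-Q-P; split from its lowest-index corner
        if (min(p, Q) < min(q, P)) list(c(p, q, Q), c(p, Q, P))
        else list(c(q, Q, P), c(q, P, p))
      }
      ft <- c(list(c(a, b, c_), c(A, C, B)),
              quad_t(a, b, A, B), quad_t(b, c_, B, C), quad_t(c_, a, C, A))
      for (f in ft) tets <- rbind(tets, c(f, m))
    }
  }
  nodes <- rbind(nodes, extra)
  vol <- tet_volumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]

  # boundary facets
  pat <- list()
  for (iz in seq_len(n_z)) {
    lo <- (iz - 1L) * n_slice; hi <- iz * n_slice
    for (it in seq_len(n_theta)) {
      a <- ring_id(n_r, it) + lo; b <- ring_id(n_r, it + 1L) + lo
      A <- ring_id(n_r, it) + hi; B <- ring_id(n_r, it + 1L) + hi
      if (min(a, B) < min(b, A)) {
        pat[[length(pat) + 1L]] <- rbind(c(a, b, B), c(a, B, A))
      } else {
        pat[[length(pat) + 1L]] <- rbind(c(b, B, A), c(b, A, a))
      }
    }
  }
  wall <- do.call(rbind, pat)
  cap <- function(iz) {
    lo <- (iz - 1L) * n_slice
    tri + lo
  }
  inlet <- cap(1L)[, c(1L, 3L, 2L), drop = FALSE]  # outward normal -z
  outlet <- cap(n_z + 1L)
  patches <- rbind(
    data.frame(n1 = wall[, 1], n2 = wall[, 2], n3 = wall[, 3], label = "wall"),
    data.frame(n1 = inlet[, 1], n2 = inlet[, 2], n3 = inlet[, 3],
               label = "inlet"),
    data.frame(n1 = outlet[, 1], n2 = outlet[, 2], n3 = outlet[, 3],
               label = "outlet")
  )
  wall_nodes <- sort(unique(as.vector(wall)))
  structure(list(nodes = unname(nodes), tets = unname(tets), patches = patches,
                 wall_nodes = wall_nodes,
                 open_nodes = setdiff(sort(unique(as.vector(rbind(inlet, outlet)))),
                                      wall_nodes),
                 radius = radius, length = length, level = 1L),
            class = "fluid_mesh")
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' @param radius Sphere radius (mm).
#' @param level Subdivision level (0 = icosahedron, each level quadrisects).
#' @return List with `nodes` and outward-oriented `tris`.
#' @export
icosphere <- function(radius = 0.5, level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  nodes <- v / sqrt(rowSums(v^2))
  tris <- f
  for (i in seq_len(level)) {
    sub <- .subdivide_tris(nodes, tris)
    nodes <- sub$nodes / sqrt(rowSums(sub$nodes^2))
    tris <- sub$tris
  }
  # orient outward
  cen <- (nodes[tris[, 1], ] + nodes[tris[, 2], ] + nodes[tris[, 3], ]) / 3
  e1 <- nodes[tris[, 2], ] - nodes[tris[, 1], ]
  e2 <- nodes[tris[, 3], ] - nodes[tris[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  flip <- rowSums(nrm * cen) < 0
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  list(nodes = nodes * radius, tris = tris)
}

#' Generate the fluid and solid meshes for a geometry
#'
#' @param geom An `acinus_geometry` with scenario applied.
#' @param resolution Refinement level (1-3); level 1 stays well under the
#'   desk budget of 5e4 fluid cells / 3e4 solid triangles.
#' @return List with elements `fluid` (a `fluid_mesh`) and `solid`
#'   (a `shell_mesh`, or a tube wall description for the degenerate tube).
#' @export
generate_meshes <- function(geom, resolution = 1L) {
  stopifnot(inherits(geom, "acinus_geometry"))
  if (geom$kind == "tube") {
    fl <- tube_mesh(geom$radius, geom$length,
                    n_r = 4L + 2L * resolution,
                    n_theta = 8L * (resolution + 1L),
                    n_z = 4L * (resolution + 1L),
                    wall_layers = if (resolution >= 2L) 2L else 0L)
    return(list(fluid = fl, solid = NULL))
  }
  fl <- build_fluid_mesh(geom, level = resolution)
  sl <- build_shell_mesh(geom, level = resolution)
  bad <- which(tet_volumes(fl$nodes, fl$tets) <= 0)
  if (length(bad)) {
    stop_acinusim(paste("inverted fluid elements:",
                        paste(utils::head(bad, 10L), collapse = ", ")),
                  "acinusim_meshing_error", elements = bad)
  }
  list(fluid = fl, solid = sl)
}

#' Validate a tetrahedral mesh
#'
#' Checks element orientation (positive volumes) and that every boundary
#' facet carries exactly one patch label.
#'
#' @param mesh A `fluid_mesh`.
#' @return List with `ok`, `min_volume`, `n_unlabelled`.
#' @export
check_mesh <- function(mesh) {
  vol <- tet_volumes(mesh$nodes, mesh$tets)
  fk <- function(a, b, c_) {
    m <- cbind(a, b, c_)
    m <- t(apply(m, 1L, sort))
    paste(m[, 1], m[, 2], m[, 3])
  }
  f_all <- rbind(mesh$tets[, c(1, 2, 3)], mesh$tets[, c(1, 2, 4)],
                 mesh$tets[, c(1, 3, 4)], mesh$tets[, c(2, 3, 4)])
  keys <- fk(f_all[, 1], f_all[, 2], f_all[, 3])
  tab <- table(keys)
  bnd_keys <- names(tab)[tab == 1L]
  lab_keys <- fk(mesh$patches$n1, mesh$patches$n2, mesh$patches$n3)
  n_unlab <- length(setdiff(bnd_keys, lab_keys))
  list(ok = all(vol > 0) && n_unlab == 0L,
       min_volume = min(vol), n_unlabelled = n_unlab)
}
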