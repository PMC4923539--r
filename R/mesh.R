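#' Convert a label map to a voxel hexahedral mesh
#'
#' One 8-node hexahedral element per foreground voxel (label != 0), with node
#' deduplication across shared corners and a consistent right-handed corner
#' ordering (VTK hexahedron convention), giving positive Jacobians everywhere.
#'
#' @param labels a (cleaned) [label_map()].
#' @return an object of class `hex_mesh`: node coordinates (`nodes`, mm),
#'   element connectivity (`elems`, 8 node ids per row), per-element `label`
#'   and source `voxel_index`, the lattice pitch `h` and the grid metadata
#'   needed to locate boundary planes.
#' @export
voxels_to_hexmesh <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  d <- labels$dims
  fg <- which(labels$labels != 0L)
  if (length(fg) == 0L) stop("no foreground voxels to mesh")
  ijk0 <- arrayInd(fg, d) - 1L   # 0-based voxel indices
  nd <- d + 1L                   # lattice node grid
  # VTK hexahedron corner order
  corner <- matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L,
                     0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, 1L),
                   ncol = 3L, byrow = TRUE)
  gid <- matrix(0L, nrow(ijk0), 8L)
  for (c8 in 1:8) {
    gid[, c8] <- (ijk0[, 1] + corner[c8, 1]) +
      nd[1] * ((ijk0[, 2] + corner[c8, 2]) +
                 nd[2] * (ijk0[, 3] + corner[c8, 3])) + 1L
  }
  used <- sort(unique(as.vector(gid)))
  remap <- integer(prod(nd)); remap[used] <- seq_along(used)
  elems <- matrix(remap[gid], ncol = 8L)
  u0 <- used - 1L
  gi <- u0 %% nd[1]
  gj <- (u0 %/% nd[1]) %% nd[2]
  gk <- u0 %/% (nd[1] * nd[2])
  nodes <- cbind(labels$origin[1] + gi * labels$spacing[1],
                 labels$origin[2] + gj * labels$spacing[2],
                 labels$origin[3] + gk * labels$spacing[3])
  structure(
    list(nodes = nodes, elems = elems,
         label = as.integer(labels$labels[fg]), voxel_index = fg,
         h = labels$spacing[1], dims = d, node_grid = cbind(gi, gj, gk),
         spacing = labels$spacing, origin = labels$origin,
         E = NULL, nu = NULL),
    class = "hex_mesh"
  )
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat("<hex_mesh> ", nrow(x$elems), " elements, ", nrow(x$nodes),
      " nodes, h = ", x$h, " mm\n", sep = "")
  invisible(x)
}

#' Material tables for the two model variants
#'
#' Refined (microstructural) model: trabecular and cortical bone share one
#' material, E = 14400 MPa, nu = 0.309; implant (titanium) E = 110000 MPa,
#' nu = 0.35. Simplified (homogenized) model: cortical 14400 MPa / 0.309,
#' cancellous block 480 MPa / 0.225, implant 110000 MPa / 0.35. Units are
#' mm / N / MPa throughout.
#'
#' @param variant `"refined"` or `"simplified"`.
#' @return a named list mapping label to `c(E, nu)`.
#' @export
material_table <- function(variant = c("refined", "simplified")) {
  variant <- match.arg(variant)
  bone <- c(E = 14400, nu = 0.309)
  implant <- c(E = 110000, nu = 0.35)
  if (variant == "refined") {
    list(`1` = bone, `2` = bone, `3` = implant, `4` = bone)
  } else {
    list(`1` = bone, `2` = bone, `3` = implant,
         `4` = c(E = 480, nu = 0.225))
  }
}

#' Attach per-element material parameters
#'
#' @param mesh a `hex_mesh`.
#' @param table a label -> `c(E, nu)` map as from [material_table()].
#' @param variant convenience: when `table` is missing, use
#'   `material_table(variant)`.
#' @return the mesh with `E` (MPa) and `nu` filled per element.
#' @export
assign_materials <- function(mesh, table = NULL,
                             variant = c("refined", "simplified")) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (is.null(table)) table <- material_table(match.arg(variant))
  labs <- as.character(sort(unique(mesh$label)))
  miss <- setdiff(labs, names(table))
  if (length(miss)) {
    stop("material table is missing labels: ", paste(miss, collapse = ", "))
  }
  Emap <- vapply(table, `[[`, numeric(1), "E")
  numap <- vapply(table, `[[`, numeric(1), "nu")
  if (any(Emap <= 0) || any(numap <= 0) || any(numap >= 0.5)) {
    stop("materials must satisfy E > 0 and 0 < nu < 0.5")
  }
  key <- as.character(mesh$label)
  mesh$E <- unname(Emap[key])
  mesh$nu <- unname(numap[key])
  mesh
}

#' Implant-bone interface elements
#'
#' The bone elements (labels 1, 2 or 4) sharing at least one face with an
#' implant element (face adjacency on the voxel lattice). Implant elements are
#' excluded: the interface statistics are taken on the bone around the
#' implant.
#'
#' @param mesh a `hex_mesh`.
#' @return an integer vector of element ids (row indices into `mesh$elems`).
#' @export
find_interface <- function(mesh) {
  stopifnot(inherits(mesh, "hex_mesh"))
  d <- mesh$dims
  imp <- array(FALSE, dim = d)
  imp[mesh$voxel_index[mesh$label == 3L]] <- TRUE
  if (!any(imp)) stop("mesh contains no implant elements")
  bone_el <- which(mesh$label %in% c(1L, 2L, 4L))
  if (!length(bone_el)) stop("mesh contains no bone elements")
  ijk <- arrayInd(mesh$voxel_index[bone_el], d)
  offs <- neighbor_offsets(6L)
  hit <- rep(FALSE, length(bone_el))
  for (o in seq_len(nrow(offs))) {
    jx <- ijk[, 1] + offs[o, 1]; jy <- ijk[, 2] + offs[o, 2]
    jz <- ijk[, 3] + offs[o, 3]
    ok <- jx >= 1L & jx <= d[1] & jy >= 1L & jy <= d[2] & jz >= 1L & jz <= d[3]
    hit[ok] <- hit[ok] | imp[cbind(jx[ok], jy[ok], jz[ok])]
  }
  bone_el[hit]
}

#' Boundary and loading conditions
#'
#' Fixes all displacement components of every node on the two domain faces
#' normal to the specimen long axis (the mesial and distal borders,
#' representing continuity within the mandible), and applies a total axial
#' load to the implant nodes on the most-superior exposed implant faces,
#' split equally per implant. By default each implant carries the full load
#' (50 N, directed along `-axis`).
#'
#' @param mesh a `hex_mesh` containing implant elements.
#' @param load_N load magnitude in newtons (default 50).
#' @param axis unit 3-vector of the implant long axis (load applied along
#'   `-axis`); default `c(0, 0, 1)` (vertical).
#' @param long_axis index (1, 2 or 3) of the specimen long (mesial-distal)
#'   axis; default 1.
#' @param per_implant if `TRUE` (default) each implant receives the full
#'   `load_N`; if `FALSE` the implants share it equally.
#' @return an object of class `boundary_conditions`: `fixed_nodes`,
#'   a `constraints` data frame (node, comp, value), per-node force matrix
#'   `force` (N x 3) and the bookkeeping needed for reports.
#' @export
build_bcs <- function(mesh, load_N = 50, axis = c(0, 0, 1), long_axis = 1L,
                      per_implant = TRUE) {
  stopifnot(inherits(mesh, "hex_mesh"))
  g <- mesh$node_grid[, long_axis]
  fixed_nodes <- which(g == 0L | g == mesh$dims[long_axis])
  if (!length(fixed_nodes)) stop("no nodes on the mesial/distal planes")

  d <- mesh$dims
  imp_el <- which(mesh$label == 3L)
  if (!length(imp_el)) stop("mesh contains no implant elements")
  impmask <- array(FALSE, dim = d)
  impmask[mesh$voxel_index[imp_el]] <- TRUE
  comp <- connected_components_3d(impmask, 6L)
  n_imp <- max(comp)

  ax <- which.max(abs(axis))          # lattice axis closest to the load axis
  force <- matrix(0, nrow(mesh$nodes), 3L)
  load_sets <- list()
  for (ci in seq_len(n_imp)) {
    vox <- which(comp == ci)
    ijk <- arrayInd(vox, d)
    # exposed superior faces: no implant voxel above (along +ax)
    up <- ijk; up[, ax] <- up[, ax] + 1L
    inside <- up[, ax] <= d[ax]
    has_imp_above <- rep(FALSE, length(vox))
    has_imp_above[inside] <- impmask[up[inside, , drop = FALSE]]
    exposed <- !has_imp_above
    topk <- max(ijk[exposed, ax])
    top_vox <- vox[exposed & ijk[, ax] == topk]
    el <- imp_el[match(top_vox, mesh$voxel_index[imp_el])]
    # the 4 nodes of each top face: nodes of those elements on the superior
    # lattice plane topk (0-based node index == topk)
    nd_ids <- unique(as.vector(mesh$elems[el, ]))
    nd_ids <- nd_ids[mesh$node_grid[nd_ids, ax] == topk]
    if (!length(nd_ids)) stop("empty load node set for an implant")
    share <- if (per_implant) load_N else load_N / n_imp
    fvec <- -axis / sqrt(sum(axis^2)) * share / length(nd_ids)
    force[nd_ids, ] <- force[nd_ids, ] +
      matrix(fvec, length(nd_ids), 3L, byrow = TRUE)
    load_sets[[ci]] <- nd_ids
  }
  load_nodes <- sort(unique(unlist(load_sets)))
  if (any(load_nodes %in% fixed_nodes)) {
    stop("load nodes overlap the fixed mesial/distal planes")
  }
  constraints <- data.frame(
    node = rep(fixed_nodes, each = 3L),
    comp = rep(1:3, times = length(fixed_nodes)),
    value = 0
  )
  structure(
    list(fixed_nodes = fixed_nodes, load_nodes = load_nodes,
         load_sets = load_sets, constraints = constraints, force = force,
         total_force_N = colSums(force), long_axis = long_axis),
    class = "boundary_conditions"
  )
}
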