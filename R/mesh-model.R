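#' Tetrahedral mesh container
#'
#' A `mesh_model` holds the geometric domain every field in the simulator
#' lives on: node coordinates in mm, tetrahedral connectivity (4-node linear
#' or 10-node quadratic), a region label per element (`"bone"` or
#' `"implant"`), and named boundary facet sets (triangles given by their
#' corner nodes) used for constraints, tractions and electrodes.
#'
#' @param nodes numeric matrix, one row per node, columns x/y/z in mm.
#' @param tets integer matrix, one row per element; 4 columns (linear) or
#'   10 columns (quadratic; corners then edge midpoints (1,2), (2,3), (1,3),
#'   (1,4), (2,4), (3,4)).
#' @param region character vector of per-element labels, `"bone"` or
#'   `"implant"`.
#' @param facet_sets named list of integer matrices (3 columns), each row a
#'   boundary triangle given by corner node indices.
#' @param meta free-form list of generator metadata (fixture parameters,
#'   element zones, axes) carried along for analysis convenience.
#'
#' @return An object of class `mesh_model`.
#' @export
mesh_model <- function(nodes, tets, region = NULL, facet_sets = list(),
                       meta = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) abort("`nodes` must have 3 columns (x, y, z in mm)")
  if (!ncol(tets) %in% c(4L, 10L)) {
    abort("`tets` must have 4 (linear) or 10 (quadratic) columns")
  }
  if (is.null(region)) region <- rep("bone", nrow(tets))
  region <- as.character(region)
  if (length(region) != nrow(tets)) {
    abort("`region` must have one label per element")
  }
  if (!all(region %in% c("bone", "implant"))) {
    abort("region labels must be 'bone' or 'implant'")
  }
  structure(
    list(nodes = nodes, tets = tets, region = region,
         facet_sets = facet_sets, order = if (ncol(tets) == 4L) 1L else 2L,
         meta = meta),
    class = "mesh_model"
  )
}

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf("<mesh_model> %d nodes, %d tet%d elements (%d bone, %d implant)\n",
              nrow(x$nodes), nrow(x$tets), if (x$order == 1L) 4L else 10L,
              sum(x$region == "bone"), sum(x$region == "implant")))
  if (length(x$facet_sets)) {
    cat("facet sets:",
        paste(sprintf("%s (%d)", names(x$facet_sets),
                      vapply(x$facet_sets, nrow, 0L)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of elements / nodes
#' @param mesh a [mesh_model()].
#' @return integer count.
#' @export
n_elements <- function(mesh) nrow(mesh$tets)

#' @rdname n_elements
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' Signed element volumes (mm^3)
#'
#' Computed from the corner nodes (straight-edge geometry for quadratic
#' elements).
#' @param mesh a [mesh_model()].
#' @return numeric vector of signed volumes.
#' @export
element_volumes <- function(mesh) {
  fem_tet_volumes(mesh$nodes, mesh$tets[, 1:4, drop = FALSE])
}

#' Element centroids (corner average, mm)
#' @param mesh a [mesh_model()].
#' @return numeric matrix, one row per element.
#' @export
element_centroids <- function(mesh) {
  tt <- mesh$tets[, 1:4, drop = FALSE]
  (mesh$nodes[tt[, 1], , drop = FALSE] + mesh$nodes[tt[, 2], , drop = FALSE] +
     mesh$nodes[tt[, 3], , drop = FALSE] + mesh$nodes[tt[, 4], , drop = FALSE]) / 4
}

# Local corner faces of a tetrahedron, outward-oriented for a positively
# oriented element.
tet_face_index <- function() {
  rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))
}

# All corner faces as a (4m x 3) matrix plus owner element ids.
all_faces <- function(mesh) {
  tt <- mesh$tets[, 1:4, drop = FALSE]
  fi <- tet_face_index()
  faces <- rbind(tt[, fi[1, ]], tt[, fi[2, ]], tt[, fi[3, ]], tt[, fi[4, ]])
  owner <- rep(seq_len(nrow(tt)), times = 4L)
  list(faces = faces, owner = owner)
}

face_key <- function(faces) {
  s <- t(apply(faces, 1L, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "-")
}

#' Boundary faces of a mesh
#'
#' Faces (corner-node triangles) that belong to exactly one element, i.e.
#' the surface of the mesh.
#'
#' @param mesh a [mesh_model()].
#' @return list with `faces` (k x 3 corner node indices, outward oriented)
#'   and `owner` (owning element index per face).
#' @export
boundary_faces <- function(mesh) {
  af <- all_faces(mesh)
  key <- face_key(af$faces)
  cnt <- table(key)
  keep <- cnt[key] == 1L
  list(faces = af$faces[keep, , drop = FALSE], owner = af$owner[keep])
}

face_centroids <- function(mesh, faces) {
  (mesh$nodes[faces[, 1], , drop = FALSE] +
     mesh$nodes[faces[, 2], , drop = FALSE] +
     mesh$nodes[faces[, 3], , drop = FALSE]) / 3
}

face_areas <- function(mesh, faces) {
  a <- mesh$nodes[faces[, 1], , drop = FALSE]
  u <- mesh$nodes[faces[, 2], , drop = FALSE] - a
  v <- mesh$nodes[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Check mesh validity
#'
#' Runs the structural invariants every generated fixture must satisfy:
#' valid node references, strictly positive element volumes, a watertight
#' boundary (every boundary edge shared by exactly two boundary faces),
#' facet sets that lie on the boundary, and a region label per element.
#'
#' @param mesh a [mesh_model()].
#' @return A tibble with columns `check` and `pass`.
#' @export
check_mesh <- function(mesh) {
  tt <- mesh$tets
  idx_ok <- all(tt >= 1L) && all(tt <= nrow(mesh$nodes))
  vols <- element_volumes(mesh)
  vol_ok <- all(vols > 0)
  bf <- boundary_faces(mesh)
  edges <- rbind(bf$faces[, c(1, 2)], bf$faces[, c(2, 3)], bf$faces[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  # closed surface: every boundary edge borders an even number (>= 2) of
  # boundary faces (non-manifold edges are allowed on voxelized fixtures)
  watertight <- nrow(bf$faces) > 0 && all(table(ekey) %% 2L == 0L)
  bkey <- face_key(bf$faces)
  fs_ok <- all(vapply(mesh$facet_sets, function(f) {
    nrow(f) > 0 && all(face_key(f) %in% bkey)
  }, TRUE))
  region_ok <- length(mesh$region) == nrow(tt) &&
    all(mesh$region %in% c("bone", "implant"))
  tibble(
    check = c("node_indices", "positive_volumes", "watertight_boundary",
              "facet_sets_on_boundary", "region_labels"),
    pass = c(idx_ok, vol_ok, watertight, fs_ok, region_ok)
  )
}

#' @rdname check_mesh
#' @export
validate_mesh <- function(mesh) {
  ck <- check_mesh(mesh)
  if (!all(ck$pass)) {
    abort(paste0("mesh validity check failed: ",
                 paste(ck$check[!ck$pass], collapse = ", ")))
  }
  invisible(mesh)
}

# Swap two nodes of any negatively oriented element (corner swap 3<->4).
fix_orientation <- function(nodes, tets) {
  v <- fem_tet_volumes(nodes, tets[, 1:4, drop = FALSE])
  flip <- which(v < 0)
  if (length(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
  }
  tets
}

#' Convert a linear mesh to quadratic (tet10)
#'
#' Inserts a shared midside node on every element edge. Facet sets keep
#' their corner-node representation; the edge-to-midnode map is stored in
#' `mesh$edge_mid` so boundary loads and constraints can recover midside
#' nodes of a facet.
#'
#' @param mesh a linear (tet4) [mesh_model()].
#' @return A quadratic (tet10) `mesh_model`.
#' @export
to_quadratic <- function(mesh) {
  if (mesh$order != 1L) abort("mesh is already quadratic")
  tt <- mesh$tets
  ep <- rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L), c(1L, 4L), c(2L, 4L), c(3L, 4L))
  e1 <- cbind(tt[, ep[1, 1]], tt[, ep[1, 2]])
  edges <- do.call(rbind, lapply(seq_len(6L), function(k) {
    cbind(tt[, ep[k, 1]], tt[, ep[k, 2]])
  }))
  lo <- pmin(edges[, 1], edges[, 2])
  hi <- pmax(edges[, 1], edges[, 2])
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  ukey <- key[uk]
  mid_id <- nrow(mesh$nodes) + seq_len(sum(uk))
  names(mid_id) <- ukey
  mids <- (mesh$nodes[lo[uk], , drop = FALSE] +
             mesh$nodes[hi[uk], , drop = FALSE]) / 2
  m <- nrow(tt)
  midcols <- matrix(mid_id[key], nrow = m, ncol = 6L)
  out <- mesh_model(rbind(mesh$nodes, mids), cbind(tt, midcols),
                    region = mesh$region, facet_sets = mesh$facet_sets,
                    meta = mesh$meta)
  out$edge_mid <- mid_id
  out
}

# Midside node ids of facet triangles (quadratic meshes); NULL for linear.
facet_midside_nodes <- function(mesh, faces) {
  if (mesh$order == 1L) return(NULL)
  em <- mesh$edge_mid
  pairs <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  matrix(unname(em[key]), nrow = nrow(faces), ncol = 3L)
}

# All node ids (corners + midsides where present) touched by a facet set.
facet_nodes <- function(mesh, faces) {
  ids <- as.vector(faces)
  ms <- facet_midside_nodes(mesh, faces)
  if (!is.null(ms)) ids <- c(ids, as.vector(ms))
  sort(unique(ids))
}
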