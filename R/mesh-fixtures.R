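#' Structured block fixture
#'
#' Builds a structured tetrahedralization of a box by splitting every grid
#' cell into 6 tetrahedra around the cell's main diagonal (Kuhn split),
#' which is conforming across neighbouring cells. Used for patch tests,
#' slab electrostatics and beam-bending verification.
#'
#' @param nx,ny,nz number of cells along each axis (>= 1).
#' @param lengths numeric length-3, box edge lengths in mm.
#' @param order element order: 1 (tet4) or 2 (tet10).
#' @return A [mesh_model()] with facet sets `xmin`, `xmax`, `ymin`, `ymax`,
#'   `zmin`, `zmax`.
#' @examples
#' m <- generate_block_fixture(1, 1, 1, lengths = c(10, 10, 10))
#' n_elements(m)  # 6
#' @export
generate_block_fixture <- function(nx, ny, nz, lengths = c(1, 1, 1),
                                   order = 1L) {
  if (any(c(nx, ny, nz) < 1) || any(c(nx, ny, nz) %% 1 != 0)) {
    abort("nx, ny, nz must be integers >= 1")
  }
  if (any(lengths <= 0)) abort("box edge lengths must be positive")
  xs <- seq(0, lengths[1], length.out = nx + 1)
  ys <- seq(0, lengths[2], length.out = ny + 1)
  zs <- seq(0, lengths[3], length.out = nz + 1)
  g <- structured_grid(xs, ys, zs)
  tets <- fix_orientation(g$nodes, g$tets)
  mesh <- mesh_model(g$nodes, tets, meta = list(lengths = lengths,
                                                cells = c(nx, ny, nz)))
  mesh$facet_sets <- box_facet_sets(mesh, lengths)
  if (order == 2L) mesh <- to_quadratic(mesh)
  validate_mesh(mesh)
}

# Nodes + 6-tet Kuhn split of every cell of a structured grid. Conforming:
# all cells use the diagonal from the (0,0,0) to the (1,1,1) corner.
structured_grid <- function(xs, ys, zs) {
  nx <- length(xs) - 1L; ny <- length(ys) - 1L; nz <- length(zs) - 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  idx <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  i <- cells$i; j <- cells$j; k <- cells$k
  v <- function(di, dj, dk) idx(i + di, j + dj, k + dk)
  # Kuhn split: one tet per permutation of (x, y, z); path corners
  # c0 -> c0+e_p1 -> c0+e_p1+e_p2 -> c7.
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  e <- diag(3L)
  tets <- do.call(rbind, lapply(perms, function(p) {
    a <- e[p[1], ]; b <- e[p[1], ] + e[p[2], ]
    cbind(v(0L, 0L, 0L),
          v(a[1], a[2], a[3]),
          v(b[1], b[2], b[3]),
          v(1L, 1L, 1L))
  }))
  list(nodes = nodes, tets = tets)
}

# Face-connected (6-neighbourhood) cell component containing the bottom
# layer of the mask, grown by iterative dilation.
connected_cells <- function(mask) {
  d <- dim(mask)
  comp <- array(FALSE, dim = d)
  comp[, , 1] <- mask[, , 1]
  if (!any(comp)) {
    # anchor at the lowest occupied layer if the bottom is empty
    k0 <- which(apply(mask, 3L, any))[1]
    comp[, , k0] <- mask[, , k0]
  }
  repeat {
    grow <- comp
    grow[-1, , ] <- grow[-1, , ] | comp[-d[1], , ]
    grow[-d[1], , ] <- grow[-d[1], , ] | comp[-1, , ]
    grow[, -1, ] <- grow[, -1, ] | comp[, -d[2], ]
    grow[, -d[2], ] <- grow[, -d[2], ] | comp[, -1, ]
    grow[, , -1] <- grow[, , -1] | comp[, , -d[3]]
    grow[, , -d[3]] <- grow[, , -d[3]] | comp[, , -1]
    grow <- grow & mask
    if (identical(grow, comp)) break
    comp <- grow
  }
  comp
}

box_facet_sets <- function(mesh, lengths) {
  bf <- boundary_faces(mesh)
  fc <- face_centroids(mesh, bf$faces)
  tol <- 1e-9 * max(lengths)
  pick <- function(keep) bf$faces[keep, , drop = FALSE]
  list(
    xmin = pick(abs(fc[, 1]) < tol),
    xmax = pick(abs(fc[, 1] - lengths[1]) < tol),
    ymin = pick(abs(fc[, 2]) < tol),
    ymax = pick(abs(fc[, 2] - lengths[2]) < tol),
    zmin = pick(abs(fc[, 3]) < tol),
    zmax = pick(abs(fc[, 3] - lengths[3]) < tol)
  )
}

#' Parameters for the parametric proximal-femur fixture
#'
#' Dimensions are in mm. The fixture is a simplified proximal femur: a
#' vertical shaft, an angled neck and a spherical head, meshed as a
#' structured tetrahedral grid clipped to the implicit solid (in the spirit
#' of voxel-based micro-FE bone models). The implanted variant removes the
#' head and labels a stem region (down the neck axis and the medullary
#' canal) as implant; intact and implanted variants share one grid, so the
#' common bone elements coincide exactly.
#'
#' @param shaft_length shaft height (default 120).
#' @param shaft_outer_radius outer shaft radius (default 16).
#' @param shaft_inner_radius medullary canal radius (default 7).
#' @param neck_length neck axis length (default 50).
#' @param neck_radius neck radius (default 13).
#' @param neck_angle angle of the neck axis from the proximal shaft axis,
#'   degrees (default 50, i.e. a 130 degree neck-shaft angle).
#' @param head_radius femoral head radius (default 23).
#' @param target_element_count approximate number of tetrahedra of the
#'   intact variant (default 12000).
#' @param implanted logical; build the post-arthroplasty variant.
#' @param implant_stem_radius stem radius (default 6; must fit the canal).
#' @param implant_stem_length stem length down the canal from the shaft top
#'   (default 80; must be shorter than the shaft).
#' @param jitter_frac node jitter amplitude as a fraction of grid spacing
#'   (default 0; capped at 0.15 to keep elements valid).
#' @param seed RNG seed for the jitter.
#' @return A named list of fixture parameters.
#' @export
femur_fixture_params <- function(shaft_length = 120, shaft_outer_radius = 16,
                                 shaft_inner_radius = 7, neck_length = 50,
                                 neck_radius = 13, neck_angle = 50,
                                 head_radius = 23,
                                 target_element_count = 12000,
                                 implanted = FALSE, implant_stem_radius = 6,
                                 implant_stem_length = 80, jitter_frac = 0,
                                 seed = 1L) {
  p <- list(shaft_length = shaft_length,
            shaft_outer_radius = shaft_outer_radius,
            shaft_inner_radius = shaft_inner_radius,
            neck_length = neck_length, neck_radius = neck_radius,
            neck_angle = neck_angle, head_radius = head_radius,
            target_element_count = target_element_count,
            implanted = implanted,
            implant_stem_radius = implant_stem_radius,
            implant_stem_length = implant_stem_length,
            jitter_frac = jitter_frac, seed = seed)
  lens <- c(p$shaft_length, p$shaft_outer_radius, p$shaft_inner_radius,
            p$neck_length, p$neck_radius, p$head_radius,
            p$implant_stem_radius, p$implant_stem_length)
  if (any(lens <= 0)) abort("all fixture lengths must be positive")
  if (p$shaft_inner_radius >= p$shaft_outer_radius) {
    abort("canal radius must be smaller than the outer shaft radius")
  }
  if (p$implanted) {
    if (p$implant_stem_radius > p$shaft_inner_radius) {
      abort("implant stem does not fit the medullary canal")
    }
    if (p$implant_stem_length >= p$shaft_length) {
      abort("implant stem must be shorter than the shaft")
    }
  }
  if (p$jitter_frac < 0 || p$jitter_frac > 0.15) {
    abort("jitter_frac must be in [0, 0.15]")
  }
  p
}

#' Generate the parametric proximal-femur fixture
#'
#' @param params a [femur_fixture_params()] list.
#' @return A [mesh_model()] with facet sets `base` (distal cut plane),
#'   `joint_patch` (joint-force application patch: top of the head when
#'   intact, the stem head at the neck cut when implanted),
#'   `greater_trochanter` (lateral muscle patch) and `neck_electrode`
#'   (circumferential band on the neck surface). Element zones
#'   (`shaft`/`neck`/`head`) and the neck axis are stored in `mesh$meta`.
#' @export
generate_proximal_femur <- function(params = femur_fixture_params()) {
  p <- do.call(femur_fixture_params, params)  # re-validate
  alpha <- p$neck_angle * pi / 180
  u <- c(sin(alpha), 0, cos(alpha))            # neck axis (unit)
  P0 <- c(0, 0, p$shaft_length)                # neck origin at shaft top
  C <- P0 + p$neck_length * u                  # head centre

  # Bounding box of the *intact* solid (shared by both variants).
  pad <- 1.0
  xr <- c(-(p$shaft_outer_radius + pad),
          max(p$shaft_outer_radius, C[1] + p$head_radius) + pad)
  ymax <- max(p$shaft_outer_radius, p$neck_radius, p$head_radius) + pad
  zr <- c(0, C[3] + p$head_radius + pad)

  vol_est <- pi * p$shaft_outer_radius^2 * p$shaft_length +
    pi * p$neck_radius^2 * p$neck_length + 4 / 3 * pi * p$head_radius^3
  h <- (6 * vol_est / p$target_element_count)^(1 / 3)

  nx <- max(3L, ceiling(diff(xr) / h))
  ny <- max(3L, ceiling(2 * ymax / h))
  nz <- max(3L, ceiling(diff(zr) / h))
  xs <- seq(xr[1], xr[2], length.out = nx + 1L)
  ys <- seq(-ymax, ymax, length.out = ny + 1L)
  zs <- seq(0, zr[2], length.out = nz + 1L)
  g <- structured_grid(xs, ys, zs)

  if (p$jitter_frac > 0) {
    hmin <- min(diff(xs)[1], diff(ys)[1], diff(zs)[1])
    jit <- withr::with_seed(p$seed, {
      matrix(stats::runif(length(g$nodes), -1, 1), ncol = 3L)
    }) * p$jitter_frac * hmin
    jit[g$nodes[, 3] < 1e-9, ] <- 0   # keep the base plane flat
    g$nodes <- g$nodes + jit
  }

  tets <- fix_orientation(g$nodes, g$tets)

  # Element selection works on whole grid cells (all 6 tets of a cell kept
  # together) and keeps only the face-connected cell component anchored at
  # the base, so no sub-body hangs on a single edge or vertex (which would
  # leave rigid zero-energy modes in the elastic solve).
  cc <- as.matrix(expand.grid(x = (head(xs, -1L) + tail(xs, -1L)) / 2,
                              y = (head(ys, -1L) + tail(ys, -1L)) / 2,
                              z = (head(zs, -1L) + tail(zs, -1L)) / 2))
  solid <- function(pts) {
    rad2 <- pts[, 1]^2 + pts[, 2]^2
    in_shaft <- rad2 <= p$shaft_outer_radius^2 & pts[, 3] <= p$shaft_length
    dC <- sweep(pts, 2L, P0)
    tt <- as.vector(dC %*% u)
    perp2 <- rowSums(dC^2) - tt^2
    in_neck <- tt >= 0 & tt <= p$neck_length & perp2 <= p$neck_radius^2
    in_head <- rowSums(sweep(pts, 2L, C)^2) <= p$head_radius^2
    list(shaft = in_shaft, neck = in_neck, head = in_head, tt = tt,
         perp2 = perp2)
  }
  sc <- solid(cc)
  inside <- if (p$implanted) sc$shaft | sc$neck else sc$shaft | sc$neck | sc$head
  mask <- array(inside, dim = c(nx, ny, nz))
  comp <- connected_cells(mask)
  keep_cells <- which(as.vector(comp))
  if (!length(keep_cells)) abort("empty fixture: target element count too small")

  ncells <- nx * ny * nz
  keep <- as.vector(outer(keep_cells, (0:5) * ncells, `+`))
  tets <- tets[keep, , drop = FALSE]
  cent <- (g$nodes[tets[, 1], ] + g$nodes[tets[, 2], ] +
             g$nodes[tets[, 3], ] + g$nodes[tets[, 4], ]) / 4
  se <- solid(cent)
  tt <- se$tt; perp2 <- se$perp2
  in_head <- se$head; in_neck <- se$neck

  # Renumber nodes to the used subset.
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(g$nodes)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  nodes <- g$nodes[used, , drop = FALSE]

  region <- rep("bone", nrow(tets))
  if (p$implanted) {
    in_stem_neck <- tt >= 0 & tt <= p$neck_length &
      perp2 <= p$implant_stem_radius^2
    in_stem_canal <- cent[, 1]^2 + cent[, 2]^2 <= p$implant_stem_radius^2 &
      cent[, 3] >= p$shaft_length - p$implant_stem_length &
      cent[, 3] <= p$shaft_length
    region[in_stem_neck | in_stem_canal] <- "implant"
    if (!any(region == "implant")) {
      abort("implanted fixture has no implant elements; refine the mesh")
    }
  }

  zone <- ifelse(in_head, "head", ifelse(in_neck, "neck", "shaft"))

  mesh <- mesh_model(nodes, tets, region = region,
                     meta = list(params = p, neck_origin = P0, neck_axis = u,
                                 head_center = C,
                                 canal_radius = p$shaft_inner_radius,
                                 canal_length = p$shaft_length,
                                 zone = zone))
  mesh$facet_sets <- femur_facet_sets(mesh, p, P0, u, C)
  validate_mesh(mesh)
}

femur_facet_sets <- function(mesh, p, P0, u, C) {
  bf <- boundary_faces(mesh)
  fc <- face_centroids(mesh, bf$faces)
  h <- (6 * max(element_volumes(mesh)))^(1 / 3)   # local element size scale
  pick <- function(keep) bf$faces[keep, , drop = FALSE]

  base <- fc[, 3] < 1e-9 * p$shaft_length + 1e-9
  dC <- sweep(fc, 2L, P0)
  tt <- as.vector(dC %*% u)
  perp <- sqrt(pmax(rowSums(dC^2) - tt^2, 0))

  if (p$implanted) {
    joint <- mesh$region[bf$owner] == "implant" & tt > p$neck_length - 1.5 * h
  } else {
    dH <- sqrt(rowSums(sweep(fc, 2L, C)^2))
    joint <- dH <= p$head_radius + 1e-9 & fc[, 3] > C[3] + 0.45 * p$head_radius
  }

  troch <- fc[, 3] >= p$shaft_length - 20 & fc[, 3] <= p$shaft_length + 1e-9 &
    fc[, 1] <= -0.55 * p$shaft_outer_radius
  electrode <- mesh$region[bf$owner] == "bone" &
    tt >= 0.3 * p$neck_length & tt <= 0.7 * p$neck_length &
    perp >= 0.6 * p$neck_radius & !base

  sets <- list(base = pick(base), joint_patch = pick(joint),
               greater_trochanter = pick(troch),
               neck_electrode = pick(electrode))
  empty <- names(sets)[vapply(sets, nrow, 0L) == 0L]
  if (length(empty)) {
    abort(paste0("empty facet set(s): ", paste(empty, collapse = ", "),
                 "; increase target_element_count"))
  }
  sets
}

#' Synthetic Hounsfield-unit field for a fixture mesh
#'
#' Emulates the CT appearance of a proximal femur: a dense cortical shell
#' near the outer surface, a mid-density cancellous interior, and a
#' low-density marrow canal, plus optional clipped Gaussian noise
#' (truncated at 3 standard deviations). Implant elements receive `NA`.
#'
#' @param mesh a [mesh_model()].
#' @param hu_cortical,hu_cancellous,hu_marrow HU levels; must satisfy
#'   `hu_marrow < hu_cancellous < hu_cortical`.
#' @param shell_thickness_mm cortical shell thickness (distance from the
#'   outer surface, base cut plane excluded).
#' @param noise_sd standard deviation of the additive noise (HU).
#' @param seed RNG seed (noise is deterministic given the seed).
#' @param canal_radius,canal_length marrow canal geometry; defaults are
#'   taken from `mesh$meta` when the mesh is a femur fixture, otherwise no
#'   marrow region is assigned.
#' @return Numeric per-element HU vector (`NA` on implant elements).
#' @export
synthetic_hu_field <- function(mesh, hu_cortical = 1700, hu_cancellous = 700,
                               hu_marrow = 100, shell_thickness_mm = 3.5,
                               noise_sd = 0, seed = 1L,
                               canal_radius = NULL, canal_length = NULL) {
  if (!(hu_marrow < hu_cancellous && hu_cancellous < hu_cortical)) {
    abort("HU levels must satisfy hu_marrow < hu_cancellous < hu_cortical")
  }
  canal_radius <- canal_radius %||% mesh$meta$canal_radius
  canal_length <- canal_length %||% mesh$meta$canal_length

  cent <- element_centroids(mesh)
  bf <- boundary_faces(mesh)
  fc <- face_centroids(mesh, bf$faces)
  outer <- fc[, 3] > min(mesh$nodes[, 3]) + 1e-9   # base cut is not surface
  surf <- fc[outer, , drop = FALSE]
  dist <- min_distance_to(cent, surf)

  hu <- rep(hu_cancellous, n_elements(mesh))
  hu[dist < shell_thickness_mm] <- hu_cortical
  if (!is.null(canal_radius) && !is.null(canal_length)) {
    marrow <- cent[, 1]^2 + cent[, 2]^2 < canal_radius^2 &
      cent[, 3] < canal_length & dist >= shell_thickness_mm
    hu[marrow] <- hu_marrow
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(length(hu), 0, noise_sd))
    noise <- pmin(pmax(noise, -3 * noise_sd), 3 * noise_sd)
    hu <- hu + noise
  }
  hu[mesh$region == "implant"] <- NA_real_
  hu
}
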