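#' Daily load cases
#'
#' A load case is one daily loading condition: a cycle count plus a joint
#' force (applied over the `joint_patch` facet set) and a muscle force
#' (applied over the `greater_trochanter` facet set), each given by a
#' magnitude in N and a direction angle in degrees. The angle is measured
#' in the coronal (x-z) plane from the proximal shaft axis; a positive
#' angle tilts the force medially (+x), a negative angle laterally, and
#' both forces point distally (compressive on the femur).
#'
#' @param name label of the condition.
#' @param cycles daily load cycles `n_j` (> 0).
#' @param joint_force_N,joint_angle_deg joint force magnitude / direction.
#' @param muscle_force_N,muscle_angle_deg muscle force magnitude / direction.
#' @param joint_set,muscle_set names of the application facet sets.
#' @return A named list of class `load_case`.
#' @export
load_case <- function(name, cycles, joint_force_N, joint_angle_deg,
                      muscle_force_N, muscle_angle_deg,
                      joint_set = "joint_patch",
                      muscle_set = "greater_trochanter") {
  if (cycles <= 0) abort("cycles must be positive")
  if (joint_force_N < 0 || muscle_force_N < 0) {
    abort("force magnitudes must be non-negative")
  }
  structure(list(name = name, cycles = cycles,
                 joint_force_N = joint_force_N,
                 joint_angle_deg = joint_angle_deg,
                 muscle_force_N = muscle_force_N,
                 muscle_angle_deg = muscle_angle_deg,
                 joint_set = joint_set, muscle_set = muscle_set),
            class = "load_case")
}

#' The three daily loading conditions
#'
#' Standing (6000 cycles, joint 2317 N at 24 deg, muscle 703 N at 28 deg),
#' hip abduction (2000 cycles, 1158 N at -15 deg, 351 N at -8 deg) and hip
#' adduction (2000 cycles, 1548 N at 56 deg, 468 N at 35 deg).
#'
#' @return A list of three [load_case()] objects.
#' @export
default_load_cases <- function() {
  list(
    load_case("standing", 6000, 2317, 24, 703, 28),
    load_case("hip_abduction", 2000, 1158, -15, 351, -8),
    load_case("hip_adduction", 2000, 1548, 56, 468, 35)
  )
}

# Force vector from magnitude + coronal-plane angle (degrees from the
# proximal shaft axis, pointing distally).
force_vector <- function(magnitude, angle_deg) {
  a <- angle_deg * pi / 180
  magnitude * c(sin(a), 0, -cos(a))
}

#' Assemble the global elastic stiffness matrix
#'
#' @param mesh a [mesh_model()].
#' @param E per-element Young's moduli (MPa).
#' @param nu Poisson's ratio (single value).
#' @return A sparse symmetric `dgCMatrix` (3 dofs per node; mm-N-MPa units).
#' @export
assemble_elastic <- function(mesh, E, nu) {
  if (length(E) != n_elements(mesh)) abort("E must have one value per element")
  if (any(!is.finite(E)) || any(E <= 0)) {
    abort("non-positive or non-finite element modulus",
          class = "osteosim_bad_material")
  }
  tr <- fem_stiffness_elastic(mesh$nodes, mesh$tets, E, nu)
  ndof <- 3L * n_nodes(mesh)
  sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(ndof, ndof))
}

# Distribute a total force as a uniform traction over a facet set.
# Consistent nodal loads: linear triangles put A/3 on each corner;
# quadratic faces put A/3 on each midside node and zero on corners.
traction_forces <- function(mesh, faces, total_force) {
  ndof <- 3L * n_nodes(mesh)
  f <- numeric(ndof)
  A <- face_areas(mesh, faces)
  t_vec <- total_force / sum(A)      # traction, N/mm^2
  ms <- facet_midside_nodes(mesh, faces)
  target <- if (is.null(ms)) faces else ms
  for (c3 in 1:3) {
    w <- A / 3 * t_vec[c3]
    for (k in 1:3) {
      dof <- 3L * (target[, k] - 1L) + c3
      agg <- tapply(w, dof, sum)
      f[as.integer(names(agg))] <- f[as.integer(names(agg))] + agg
    }
  }
  f
}

# Solve K u = f with Dirichlet values on fixed dofs; returns the full
# solution and the reactions at the fixed dofs.
solve_dirichlet <- function(K, f, fixed_dofs, fixed_values = 0) {
  ndof <- nrow(K)
  if (!length(fixed_dofs)) {
    abort("singular system: no Dirichlet constraints",
          class = "osteosim_singular_system")
  }
  fixed_values <- rep_len(fixed_values, length(fixed_dofs))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- numeric(ndof)
  u[fixed_dofs] <- fixed_values
  rhs <- f[free] - as.vector(K[free, fixed_dofs, drop = FALSE] %*% fixed_values)
  Kff <- K[free, free, drop = FALSE]
  sol <- tryCatch({
    ch <- Cholesky(methods::as(methods::as(Kff, "symmetricMatrix"), "CsparseMatrix"),
                   LDL = FALSE)
    as.vector(solve(ch, rhs, system = "A"))
  }, error = function(e) {
    abort(paste0("singular system: ", conditionMessage(e)),
          class = "osteosim_singular_system")
  })
  u[free] <- sol
  reactions <- as.vector(K[fixed_dofs, , drop = FALSE] %*% u) - f[fixed_dofs]
  list(u = u, reactions = reactions,
       residual = sqrt(sum((as.vector(Kff %*% sol) - rhs)^2)) /
         max(sqrt(sum(rhs^2)), .Machine$double.eps))
}

#' Static linear-elastic solve for one load case
#'
#' Small-strain isotropic elasticity on the mesh with zero displacement on
#' the fixed facet set and each force applied as a uniform traction over
#' its patch (resultant equal to the case's force vector).
#'
#' @param mesh a [mesh_model()].
#' @param material material-field tibble from [build_material_field()] (or
#'   any data frame with columns `E` and, optionally, `is_implant`).
#' @param case a [load_case()].
#' @param fixed_set name of the fully fixed facet set (default `"base"`).
#' @param nu Poisson's ratio.
#' @return A list of class `stress_state`: `displacement` (n x 3 matrix,
#'   mm), `stress` (tibble per element: Voigt components, principal
#'   stresses, `von_mises`), `reaction` (length-3 total base reaction, N),
#'   `applied` (length-3 total applied force), `case` and `residual`.
#' @export
assemble_and_solve <- function(mesh, material, case, fixed_set = "base",
                               nu = 0.3) {
  if (!fixed_set %in% names(mesh$facet_sets) ||
      nrow(mesh$facet_sets[[fixed_set]]) == 0) {
    abort(paste0("fixed facet set '", fixed_set, "' is missing or empty"))
  }
  for (s in c(case$joint_set, case$muscle_set)) {
    if (!s %in% names(mesh$facet_sets) || nrow(mesh$facet_sets[[s]]) == 0) {
      abort(paste0("load facet set '", s, "' is missing or empty"))
    }
  }
  E <- material$E
  K <- assemble_elastic(mesh, E, nu)
  fj <- force_vector(case$joint_force_N, case$joint_angle_deg)
  fm <- force_vector(case$muscle_force_N, case$muscle_angle_deg)
  f <- traction_forces(mesh, mesh$facet_sets[[case$joint_set]], fj) +
    traction_forces(mesh, mesh$facet_sets[[case$muscle_set]], fm)
  fixed_nodes <- facet_nodes(mesh, mesh$facet_sets[[fixed_set]])
  fixed_dofs <- as.vector(outer(3L * (fixed_nodes - 1L), 1:3, `+`))
  sol <- solve_dirichlet(K, f, fixed_dofs)
  st <- element_stress_table(mesh, E, nu, sol$u)
  rx <- rowsum_by_component(sol$reactions, fixed_dofs)
  structure(list(displacement = matrix(sol$u, ncol = 3L, byrow = TRUE),
                 stress = st, reaction = rx,
                 applied = fj + fm, case = case, residual = sol$residual),
            class = "stress_state")
}

rowsum_by_component <- function(values, dofs) {
  comp <- (dofs - 1L) %% 3L + 1L
  vapply(1:3, function(c3) sum(values[comp == c3]), 0)
}

element_stress_table <- function(mesh, E, nu, u) {
  S <- fem_element_stress(mesh$nodes, mesh$tets, E, nu, u)
  pr <- principal_stress_field(S)
  tibble(element_id = seq_len(nrow(S)),
         sxx = S[, 1], syy = S[, 2], szz = S[, 3],
         sxy = S[, 4], syz = S[, 5], szx = S[, 6],
         s1 = pr[, 1], s2 = pr[, 2], s3 = pr[, 3],
         von_mises = von_mises(pr[, 1], pr[, 2], pr[, 3]))
}

#' Principal stresses of a symmetric stress tensor
#'
#' @param tensor a symmetric 3 x 3 stress tensor (MPa).
#' @param tol absolute asymmetry tolerance.
#' @return Numeric length-3, eigenvalues sorted descending.
#' @export
principal_stresses <- function(tensor, tol = 1e-9) {
  if (!is.matrix(tensor) || any(dim(tensor) != c(3L, 3L))) {
    abort("tensor must be a 3 x 3 matrix")
  }
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor)))) {
    abort("stress tensor is not symmetric")
  }
  sort(eigen((tensor + t(tensor)) / 2, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

# Vectorized closed-form eigenvalues of symmetric 3x3 tensors in Voigt rows
# (xx, yy, zz, xy, yz, zx); returns m x 3 sorted descending.
principal_stress_field <- function(S) {
  sxx <- S[, 1]; syy <- S[, 2]; szz <- S[, 3]
  sxy <- S[, 4]; syz <- S[, 5]; szx <- S[, 6]
  p1 <- sxy^2 + syz^2 + szx^2
  q <- (sxx + syy + szz) / 3
  p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(q, nrow = length(q), ncol = 3L)
  nz <- p > .Machine$double.eps * pmax(1, abs(q))
  if (any(nz)) {
    bxx <- (sxx - q) / p; byy <- (syy - q) / p; bzz <- (szz - q) / p
    bxy <- sxy / p; byz <- syz / p; bzx <- szx / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bzx) +
      bzx * (bxy * byz - byy * bzx)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    out[nz, 1] <- e1[nz]; out[nz, 2] <- e2[nz]; out[nz, 3] <- e3[nz]
  }
  out
}

#' Von Mises equivalent stress
#'
#' `sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))`; invariant to a
#' hydrostatic offset.
#'
#' @param s1,s2,s3 principal stresses (MPa), vectorized.
#' @return equivalent stress (MPa).
#' @export
von_mises <- function(s1, s2, s3) {
  sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2))
}
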