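#' Anisotropic dielectric parameters of bone
#'
#' Bone's dielectric tensor is diagonal in the material frame:
#' `diag(b11, b11, b33)` with the transverse permittivity `b11` on the two
#' axes orthogonal to the shaft and the longitudinal permittivity `b33` on
#' the shaft axis.
#'
#' @param beta11 transverse permittivity (F/m), default 88.54e-12.
#' @param beta33 longitudinal permittivity (F/m), default 106.248e-12.
#' @param axis unit vector of the material (shaft) axis, default mesh z.
#' @return A list of class `dielectric_params`.
#' @export
dielectric_params <- function(beta11 = 88.54e-12, beta33 = 106.248e-12,
                              axis = c(0, 0, 1)) {
  if (beta11 <= 0 || beta33 <= 0) abort("permittivities must be positive")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(beta11 = beta11, beta33 = beta33, axis = axis),
            class = "dielectric_params")
}

# 3x3 dielectric tensor in mesh coordinates.
dielectric_tensor <- function(params) {
  a <- params$axis
  params$beta11 * diag(3) + (params$beta33 - params$beta11) * tcrossprod(a)
}

#' Electrostatic stimulation protocol
#'
#' The electrode voltage is held on the `neck_electrode` facet set and the
#' ground (0 V) on the `base`. The amplitude `A` scales how strongly the
#' normalized potential suppresses the disuse activation frequency inside
#' the stimulation window.
#'
#' @param voltage_V electrode voltage (default 32 V).
#' @param amplitude modulation amplitude `A` in `[0, 1]` (cases 0, 0.3,
#'   0.5, 0.7).
#' @param start_day first stimulation day (default 101).
#' @param duration_days stimulation duration in days (`Inf` = rest of run).
#' @param electrode_set,ground_set facet set names (must be disjoint).
#' @return A list of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(voltage_V = 32, amplitude = 0,
                                 start_day = 101, duration_days = Inf,
                                 electrode_set = "neck_electrode",
                                 ground_set = "base") {
  if (amplitude < 0 || amplitude > 1) abort("amplitude must lie in [0, 1]")
  if (start_day < 1) abort("start_day must be >= 1")
  if (duration_days < 0) abort("duration_days must be >= 0")
  if (identical(electrode_set, ground_set)) {
    abort("electrode and ground facet sets must be disjoint")
  }
  structure(list(voltage_V = voltage_V, amplitude = amplitude,
                 start_day = start_day, duration_days = duration_days,
                 electrode_set = electrode_set, ground_set = ground_set),
            class = "stimulation_protocol")
}

in_stimulation_window <- function(day, protocol) {
  !is.null(protocol) && protocol$amplitude > 0 &&
    day >= protocol$start_day &&
    day < protocol$start_day + protocol$duration_days
}

#' Solve the electrostatic boundary-value problem
#'
#' Solves `div(beta grad(phi)) = 0` with the electrode voltage on the
#' electrode facet set, 0 V on the ground set and natural (zero-flux)
#' conditions elsewhere. A single static solve is reused for all
#' stimulation days; the implant carries the bone dielectric by default.
#'
#' @param mesh a [mesh_model()].
#' @param dielectric a [dielectric_params()].
#' @param protocol a [stimulation_protocol()].
#' @param scale optional per-element multiplier of the dielectric tensor
#'   (used for layered verification fixtures).
#' @return A list of class `potential_field`: `phi` (nodal potential, V),
#'   `phi_element` (per-element nodal mean, V), `phi_hat` (per-element
#'   normalized potential in `[0, 1]`) and `residual`.
#' @export
solve_electrostatics <- function(mesh, dielectric = dielectric_params(),
                                 protocol = stimulation_protocol(),
                                 scale = NULL) {
  for (s in c(protocol$electrode_set, protocol$ground_set)) {
    if (!s %in% names(mesh$facet_sets) || nrow(mesh$facet_sets[[s]]) == 0) {
      abort(paste0("facet set '", s, "' is missing or empty"),
            class = "osteosim_missing_facet_set")
    }
  }
  if (is.null(scale)) scale <- rep(1, n_elements(mesh))
  tensor <- dielectric_tensor(dielectric)
  tr <- fem_stiffness_laplace(mesh$nodes, mesh$tets, tensor, scale)
  K <- sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                    dims = c(n_nodes(mesh), n_nodes(mesh)))
  el_nodes <- facet_nodes(mesh, mesh$facet_sets[[protocol$electrode_set]])
  gr_nodes <- setdiff(facet_nodes(mesh, mesh$facet_sets[[protocol$ground_set]]),
                      el_nodes)
  fixed <- c(el_nodes, gr_nodes)
  vals <- c(rep(protocol$voltage_V, length(el_nodes)),
            rep(0, length(gr_nodes)))
  sol <- solve_dirichlet(K, numeric(n_nodes(mesh)), fixed, vals)
  phi <- sol$u
  phi_el <- element_nodal_mean(mesh, phi)
  structure(list(phi = phi, phi_element = phi_el,
                 phi_hat = normalize_potential(phi_el),
                 residual = sol$residual, protocol = protocol),
            class = "potential_field")
}

element_nodal_mean <- function(mesh, nodal) {
  tt <- mesh$tets
  rowMeans(matrix(nodal[tt], nrow = nrow(tt)))
}

#' Normalize a potential field to the unit interval
#'
#' The region of highest potential has influence 1, the lowest 0:
#' `phi_hat = (phi - min) / (max - min)` on per-element values. A constant
#' field maps to all zeros with a warning.
#'
#' @param phi_element per-element potential (V).
#' @return normalized per-element potential in `[0, 1]`.
#' @export
normalize_potential <- function(phi_element) {
  r <- range(phi_element)
  if (diff(r) == 0) {
    warning("degenerate potential field (constant); phi_hat set to 0")
    return(rep(0, length(phi_element)))
  }
  (phi_element - r[1]) / (r[2] - r[1])
}
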