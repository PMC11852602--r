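#' Material mapping parameters
#'
#' Parameters of the CT-number to bone-material mapping: a linear HU to
#' apparent-density ramp between model-wide bounds, the cubic
#' density-to-modulus law `E = 3790 * rho^3` (MPa for rho in g/cm^3), and
#' the density-porosity relation `rho = (1 - P) * rho0`.
#'
#' @param rho_a,rho_b minimum / maximum apparent density (g/cm^3) assigned
#'   at `hu_min` / `hu_max`.
#' @param rho_0 zero-porosity (maximum) bone density (g/cm^3).
#' @param hu_min,hu_max CT bounds of the model (HU).
#' @param nu Poisson's ratio of bone (dimensionless).
#' @param n_bins number of discrete material levels (the material gradient).
#' @param cortical_threshold density (g/cm^3) above which an element is
#'   classified cortical.
#' @param implant_E,implant_nu implant modulus (MPa) and Poisson's ratio
#'   (titanium-alloy class defaults).
#' @param porosity_clamp length-2 porosity bounds enforced during
#'   remodeling, keeping stiffness strictly positive.
#' @return A named list of class `material_mapping`.
#' @export
material_mapping <- function(rho_a = 0.1, rho_b = 1.8, rho_0 = 1.8,
                             hu_min = 0, hu_max = 1700, nu = 0.3,
                             n_bins = 50L, cortical_threshold = 1.3,
                             implant_E = 110000, implant_nu = 0.3,
                             porosity_clamp = c(0.01, 0.99)) {
  if (!(rho_a < rho_b && rho_b <= rho_0)) {
    abort("require rho_a < rho_b <= rho_0")
  }
  if (hu_min >= hu_max) abort("require hu_min < hu_max",
                              class = "osteosim_degenerate_mapping")
  if (nu <= 0 || nu >= 0.5) abort("Poisson's ratio must lie in (0, 0.5)")
  if (n_bins < 1) abort("n_bins must be >= 1")
  if (!(cortical_threshold > rho_a && cortical_threshold < rho_b)) {
    abort("cortical_threshold must lie inside (rho_a, rho_b)")
  }
  structure(list(rho_a = rho_a, rho_b = rho_b, rho_0 = rho_0,
                 hu_min = hu_min, hu_max = hu_max, nu = nu,
                 n_bins = as.integer(n_bins),
                 cortical_threshold = cortical_threshold,
                 implant_E = implant_E, implant_nu = implant_nu,
                 porosity_clamp = porosity_clamp),
            class = "material_mapping")
}

#' CT number to apparent density
#'
#' Linear ramp `rho = rho_a + (rho_b - rho_a) * (HU - HUmin)/(HUmax - HUmin)`.
#' Out-of-range HU values are clamped to the bounds; the number of clamped
#' values is reported via a message when nonzero.
#'
#' @param hu numeric HU values (`NA` allowed for implant elements).
#' @param mapping a [material_mapping()].
#' @return densities in g/cm^3.
#' @export
hu_to_density <- function(hu, mapping = material_mapping()) {
  if (mapping$hu_max == mapping$hu_min) {
    abort("degenerate HU mapping (hu_max == hu_min)",
          class = "osteosim_degenerate_mapping")
  }
  n_clamped <- sum(hu < mapping$hu_min | hu > mapping$hu_max, na.rm = TRUE)
  if (n_clamped > 0) {
    message(sprintf("hu_to_density: clamped %d out-of-range HU value(s)",
                    n_clamped))
  }
  hu <- pmin(pmax(hu, mapping$hu_min), mapping$hu_max)
  mapping$rho_a + (mapping$rho_b - mapping$rho_a) *
    (hu - mapping$hu_min) / (mapping$hu_max - mapping$hu_min)
}

#' Density to Young's modulus
#'
#' Cubic law `E = 3790 * rho^3` (MPa, rho in g/cm^3).
#'
#' @param rho_t apparent densities (g/cm^3, >= 0).
#' @return moduli in MPa.
#' @export
density_to_modulus <- function(rho_t) {
  if (any(rho_t < 0, na.rm = TRUE)) abort("density must be non-negative")
  3790 * rho_t^3
}

#' Density / porosity conversions
#'
#' `rho = (1 - P) * rho0`, inverted as `P = 1 - rho/rho0`. The round trip is
#' exact.
#'
#' @param rho_t densities (g/cm^3), `0 <= rho_t <= rho_0`.
#' @param p_t porosities in `[0, 1]`.
#' @param rho_0 zero-porosity density (g/cm^3).
#' @return `density_to_porosity()` returns porosities; `porosity_to_density()`
#'   returns densities.
#' @export
density_to_porosity <- function(rho_t, rho_0 = 1.8) {
  if (any(rho_t > rho_0 + 1e-12, na.rm = TRUE)) {
    abort("density exceeds the zero-porosity density rho_0")
  }
  if (any(rho_t < 0, na.rm = TRUE)) abort("density must be non-negative")
  1 - rho_t / rho_0
}

#' @rdname density_to_porosity
#' @export
porosity_to_density <- function(p_t, rho_0 = 1.8) {
  if (any(p_t < 0 | p_t > 1, na.rm = TRUE)) {
    abort("porosity must lie in [0, 1]")
  }
  (1 - p_t) * rho_0
}

#' Quantize a density field to discrete material levels
#'
#' Densities are snapped to the midpoints of `n_bins` equal-width bins over
#' the field's range (the "material gradient"). Idempotent; a constant
#' field is returned unchanged.
#'
#' @param rho density field (g/cm^3; `NA` entries pass through).
#' @param n_bins number of levels (>= 1).
#' @return binned density field.
#' @export
bin_materials <- function(rho, n_bins = 50L) {
  if (n_bins < 1) abort("n_bins must be >= 1")
  ok <- !is.na(rho)
  # a field already at n_bins or fewer levels is left untouched, which
  # makes the quantization idempotent
  if (length(unique(rho[ok])) <= n_bins) return(rho)
  r <- range(rho[ok])
  w <- diff(r) / n_bins
  k <- pmin(floor((rho[ok] - r[1]) / w), n_bins - 1)
  out <- rho
  out[ok] <- r[1] + (k + 0.5) * w
  out
}

#' Classify bone elements as cortical or cancellous
#'
#' Elements at or above the density threshold are cortical, the rest
#' cancellous. Implant elements (`NA` density) get `NA`.
#'
#' @param rho density field (g/cm^3).
#' @param threshold cortical density threshold (g/cm^3).
#' @return character vector `"cortical"`/`"cancellous"` (`NA` for implant).
#' @export
classify_bone <- function(rho, threshold = 1.3) {
  ifelse(is.na(rho), NA_character_,
         ifelse(rho >= threshold, "cortical", "cancellous"))
}

#' Build the per-element material field
#'
#' Runs the full initialization pipeline on a fixture mesh: HU to density,
#' one-time binning to `n_bins` material levels, porosity and modulus from
#' the coupled laws, and the cortical/cancellous classification. Implant
#' elements carry the fixed implant modulus.
#'
#' @param mesh a [mesh_model()].
#' @param hu per-element HU (e.g. from [synthetic_hu_field()]).
#' @param mapping a [material_mapping()].
#' @return A tibble with one row per element: `element_id`, `hu`, `rho`,
#'   `porosity`, `E`, `bone_class`, `is_implant`.
#' @export
build_material_field <- function(mesh, hu, mapping = material_mapping()) {
  if (length(hu) != n_elements(mesh)) {
    abort("hu must have one value per element")
  }
  is_implant <- mesh$region == "implant"
  rho <- hu_to_density(hu, mapping)
  rho <- bin_materials(rho, mapping$n_bins)
  p <- density_to_porosity(rho, mapping$rho_0)
  p <- pmin(pmax(p, mapping$porosity_clamp[1]), mapping$porosity_clamp[2])
  rho <- porosity_to_density(p, mapping$rho_0)
  E <- density_to_modulus(rho)
  E[is_implant] <- mapping$implant_E
  tibble(
    element_id = seq_len(n_elements(mesh)),
    hu = hu,
    rho = ifelse(is_implant, NA_real_, rho),
    porosity = ifelse(is_implant, NA_real_, p),
    E = E,
    bone_class = classify_bone(ifelse(is_implant, NA_real_, rho),
                               mapping$cortical_threshold),
    is_implant = is_implant
  )
}
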