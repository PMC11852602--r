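#' Match bone elements between two meshes by nearest centroid
#'
#' For every bone element of `query`, finds the nearest bone element of
#' `ref` by centroid distance, subject to a distance cap (default 25% of
#' the local element size, estimated from the median element volume).
#' Unmatched elements get `NA` and are excluded from ratio statistics.
#'
#' @param query,ref [mesh_model()] objects (e.g. implanted and intact
#'   fixtures).
#' @param cap maximum matching distance in mm (`NULL` = 25% of local
#'   element size; `Inf` = uncapped).
#' @return A tibble with `element_id` (bone elements of `query`), `ref_id`
#'   (matched bone element of `ref`, `NA` if none within the cap) and
#'   `distance` (mm).
#' @export
match_elements <- function(query, ref, cap = NULL) {
  qb <- which(query$region == "bone")
  rb <- which(ref$region == "bone")
  if (!length(qb) || !length(rb)) abort("both meshes need bone elements")
  if (is.null(cap)) {
    h <- (6 * stats::median(abs(element_volumes(query))))^(1 / 3)
    cap <- 0.25 * h
  }
  qc <- element_centroids(query)[qb, , drop = FALSE]
  rc <- element_centroids(ref)[rb, , drop = FALSE]
  nn <- nearest_points(qc, rc, if (is.finite(cap)) cap else -1)
  tibble(element_id = qb,
         ref_id = ifelse(nn$index > 0, rb[pmax(nn$index, 1L)], NA_integer_),
         distance = nn$distance)
}

ratio_bin_edges <- function() seq(0, 2, by = 0.1)

# Bin index with (lo, hi] bins, first bin closed at 0; index 21 = overflow
# bin [2, Inf).
ratio_bin_index <- function(r) {
  k <- ceiling(round(r / 0.1, 9))
  k[r <= 0] <- 1L
  k[k < 1] <- 1L
  k[k > 20] <- 21L
  as.integer(k)
}

#' Stress-shielding ratio report
#'
#' Divides each matched bone element's post-implantation equivalent stress
#' by its intact-model value. Ratios below 1 indicate shielding. The
#' report holds per-case histograms (bin width 0.1 over `[0, 2]` plus an
#' overflow bin), the shielded fraction (ratio in 0 to 1; bin edges are
#' assigned to the lower bin, so a ratio of exactly 1 counts as shielded),
#' a refined
#' sub-histogram of the shielded range, and region-restricted means.
#' Elements whose intact stress falls below the denominator floor are
#' excluded and counted separately.
#'
#' @param vm_intact,vm_implanted matrices (elements x cases) of von Mises
#'   stress on the intact and implanted meshes.
#' @param matching matching tibble from [match_elements()] (implanted ->
#'   intact).
#' @param mesh optional implanted [mesh_model()]; provides element zones
#'   for the region means.
#' @param cases case names (defaults to the columns of `vm_implanted`).
#' @param floor denominator floor (MPa).
#' @return A list of class `shielding_report`: `ratios`, `histogram`,
#'   `sub_histogram`, `fractions`, `region_means`, `n_excluded`.
#' @export
stress_ratio_report <- function(vm_intact, vm_implanted, matching,
                                mesh = NULL, cases = NULL, floor = 1e-6) {
  cases <- cases %||% colnames(vm_implanted) %||%
    paste0("case", seq_len(ncol(vm_implanted)))
  ok <- !is.na(matching$ref_id)
  if (!any(ok)) abort("zero matched elements")
  el <- matching$element_id[ok]
  ref <- matching$ref_id[ok]
  zone <- if (!is.null(mesh) && !is.null(mesh$meta$zone)) {
    mesh$meta$zone[el]
  } else rep(NA_character_, length(el))

  ratios <- purrr::map_dfr(seq_along(cases), function(j) {
    den <- vm_intact[ref, j]
    keep <- den >= floor
    tibble(case = cases[j], element_id = el[keep], zone = zone[keep],
           ratio = vm_implanted[el[keep], j] / den[keep])
  })
  n_excluded <- length(el) * length(cases) - nrow(ratios)

  histogram <- ratios |>
    dplyr::mutate(bin = ratio_bin_index(.data$ratio)) |>
    dplyr::count(.data$case, .data$bin) |>
    tidyr::complete(case = cases, bin = 1:21, fill = list(n = 0L)) |>
    dplyr::group_by(.data$case) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = (.data$bin - 1) * 0.1,
                  bin_hi = ifelse(.data$bin == 21, Inf, .data$bin * 0.1))

  fractions <- histogram |>
    dplyr::group_by(.data$case) |>
    dplyr::summarise(
      fraction_shielded = sum(.data$fraction[.data$bin <= 10]),
      fraction_above = sum(.data$fraction[.data$bin > 10]),
      .groups = "drop")

  sub_histogram <- ratios |>
    dplyr::filter(.data$ratio <= 1) |>
    dplyr::mutate(bin = ratio_bin_index(.data$ratio)) |>
    dplyr::count(.data$case, .data$bin) |>
    tidyr::complete(case = cases, bin = 1:10, fill = list(n = 0L)) |>
    dplyr::group_by(.data$case) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin_lo = (.data$bin - 1) * 0.1, bin_hi = .data$bin * 0.1)

  region_means <- ratios |>
    dplyr::filter(!is.na(.data$zone)) |>
    dplyr::group_by(.data$case, .data$zone) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), n = dplyr::n(),
                     .groups = "drop")

  structure(list(ratios = ratios, histogram = histogram,
                 sub_histogram = sub_histogram, fractions = fractions,
                 region_means = region_means, n_excluded = n_excluded),
            class = "shielding_report")
}

#' @export
print.shielding_report <- function(x, ...) {
  cat("<shielding_report>\n")
  print(x$fractions)
  invisible(x)
}

#' Density difference between two runs
#'
#' Per-element `delta_rho = rho_a - rho_b` at a common day, with the
#' maximum loss, per-zone means and three neck cross-section summaries
#' (slabs orthogonal to the neck axis at configurable fractions of the
#' neck length).
#'
#' @param run_a,run_b `remodel_sim` objects holding a snapshot at `day`
#'   (see [run_simulation()]), computed on the same mesh.
#' @param day snapshot day to compare.
#' @param cut_fracs fractions of the neck length at which the three
#'   sections are taken.
#' @param slab_halfwidth half-width of each section slab in mm (`NULL` =
#'   one local element size).
#' @return A list of class `density_difference`: `delta` (per element),
#'   `summary` (tibble: `max_abs_delta`, `max_loss`, `mean_delta`),
#'   `zone_means`, `sections`.
#' @export
density_difference <- function(run_a, run_b, day,
                               cut_fracs = c(0.25, 0.5, 0.75),
                               slab_halfwidth = NULL) {
  mesh <- run_a$state$mesh
  if (n_elements(mesh) != n_elements(run_b$state$mesh)) {
    abort("runs are on different meshes")
  }
  key <- as.character(day)
  if (!key %in% names(run_a$snapshots) || !key %in% names(run_b$snapshots)) {
    abort(sprintf("both runs need a snapshot at day %d", day))
  }
  delta <- run_a$snapshots[[key]] - run_b$snapshots[[key]]
  bone <- which(mesh$region == "bone")
  smry <- tibble(day = day,
                 max_abs_delta = max(abs(delta[bone])),
                 max_loss = max(pmax(delta[bone], 0)),
                 mean_delta = mean(delta[bone]))
  zone <- mesh$meta$zone
  zone_means <- if (!is.null(zone)) {
    tibble(zone = zone[bone], delta = delta[bone]) |>
      dplyr::group_by(.data$zone) |>
      dplyr::summarise(mean_delta = mean(.data$delta), n = dplyr::n(),
                       .groups = "drop")
  } else tibble(zone = character(), mean_delta = numeric(), n = integer())
  sections <- tibble(section = integer(), t_mm = numeric(),
                     mean_delta = numeric(), n = integer())
  if (!is.null(mesh$meta$neck_axis)) {
    cent <- element_centroids(mesh)
    tt <- as.vector(sweep(cent, 2L, mesh$meta$neck_origin) %*%
                      mesh$meta$neck_axis)
    L <- mesh$meta$params$neck_length
    hw <- slab_halfwidth %||%
      (6 * stats::median(abs(element_volumes(mesh))))^(1 / 3)
    sections <- purrr::map_dfr(seq_along(cut_fracs), function(k) {
      t0 <- cut_fracs[k] * L
      sel <- bone[abs(tt[bone] - t0) <= hw & zone[bone] == "neck"]
      tibble(section = k, t_mm = t0,
             mean_delta = if (length(sel)) mean(delta[sel]) else NA_real_,
             n = length(sel))
    })
  }
  structure(list(delta = delta, summary = smry, zone_means = zone_means,
                 sections = sections, day = day),
            class = "density_difference")
}
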