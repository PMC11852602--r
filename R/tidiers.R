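#' Tidy a remodeling simulation
#'
#' @param x a `remodel_sim` from [run_simulation()].
#' @param ... unused.
#' @return A long tibble: `day`, `bone_class` (or `"neck"` for the neck
#'   region mean), `mean_density` (g/cm^3), `rate` (g/(cm^3 day)).
#' @export
tidy.remodel_sim <- function(x, ...) {
  ts <- x$timeseries
  dplyr::bind_rows(
    tibble(day = ts$day, group = "cortical",
           mean_density = ts$mean_rho_cortical, rate = ts$rate_cortical),
    tibble(day = ts$day, group = "cancellous",
           mean_density = ts$mean_rho_cancellous, rate = ts$rate_cancellous),
    tibble(day = ts$day, group = "neck",
           mean_density = ts$mean_rho_neck, rate = ts$rate_neck)
  ) |> dplyr::filter(!is.na(.data$mean_density))
}

#' @rdname tidy.remodel_sim
#' @export
glance.remodel_sim <- function(x, ...) {
  ts <- x$timeseries
  last <- ts[nrow(ts), ]
  tibble(
    days = x$state$day,
    final_rho_cortical = last$mean_rho_cortical,
    final_rho_cancellous = last$mean_rho_cancellous,
    final_rho_neck = last$mean_rho_neck,
    amplitude = if (!is.null(x$state$protocol)) x$state$protocol$amplitude else 0
  )
}

#' Tidy a shielding report
#'
#' @param x a `shielding_report` from [stress_ratio_report()].
#' @param ... unused.
#' @return The per-case histogram tibble (`case`, `bin_lo`, `bin_hi`, `n`,
#'   `fraction`).
#' @export
tidy.shielding_report <- function(x, ...) {
  x$histogram |> dplyr::select("case", "bin_lo", "bin_hi", "n", "fraction")
}

#' @rdname tidy.shielding_report
#' @export
glance.shielding_report <- function(x, ...) {
  x$fractions |>
    tidyr::pivot_wider(names_from = "case",
                       values_from = c("fraction_shielded", "fraction_above"))
}

#' Plot a remodeling simulation
#'
#' Mean density (or its daily rate) against time, one line per bone class
#' plus the neck-region mean.
#'
#' @param object a `remodel_sim`.
#' @param what `"density"` or `"rate"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.remodel_sim <- function(object, what = c("density", "rate"), ...) {
  what <- match.arg(what)
  d <- tidy(object)
  if (what == "density") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$mean_density,
                                    colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "day", y = "mean density (g/cm^3)", colour = NULL)
  } else {
    ggplot2::ggplot(dplyr::filter(d, !is.na(.data$rate)),
                    ggplot2::aes(x = .data$day, y = .data$rate,
                                 colour = .data$group)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::labs(x = "day", y = "density change rate (g/(cm^3 day))",
                    colour = NULL)
  }
}

#' Plot a shielding report
#'
#' Stress-ratio histogram per load case; the shielded range (ratio at or
#' below 1) is highlighted.
#'
#' @param object a `shielding_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.shielding_report <- function(object, ...) {
  h <- object$histogram |>
    dplyr::mutate(mid = ifelse(is.finite(.data$bin_hi),
                               (.data$bin_lo + .data$bin_hi) / 2, 2.05),
                  shielded = .data$bin_lo < 1)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$fraction,
                                  fill = .data$shielded)) +
    ggplot2::geom_col(width = 0.095, show.legend = FALSE) +
    ggplot2::facet_wrap(~case) +
    ggplot2::labs(x = "stress ratio (implanted / intact)",
                  y = "fraction of elements")
}
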