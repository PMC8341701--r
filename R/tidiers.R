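#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted schedule
#'
#' One row per 3- or 4-minute segment: the fitted rate, the simulated and
#' target endpoints and the endpoint error.
#'
#' @param x A `schedule_fit`.
#' @param ... Unused.
#' @return A tibble with columns `segment`, `t_start_min`, `t_end_min`,
#'   `rate`, `simulated_mmHg`, `target_mmHg`, `endpoint_error_mmHg`, `evals`.
#' @export
tidy.schedule_fit <- function(x, ...) {
  b <- x$schedule$boundaries
  tibble::tibble(
    segment = seq_along(x$schedule$rates),
    t_start_min = b[-length(b)], t_end_min = b[-1],
    rate = x$schedule$rates,
    simulated_mmHg = x$simulated$po2_mmHg,
    target_mmHg = x$target$po2_mmHg,
    endpoint_error_mmHg = abs(x$simulated$po2_mmHg - x$target$po2_mmHg),
    evals = vapply(x$segments, function(s) s$evals, integer(1)))
}

#' One-row summary of a fitted schedule
#'
#' @inheritParams tidy.schedule_fit
#' @return A tibble with `kind`, `gof`, `gof_form`, `max_rate`, `min_rate`,
#'   `total_evals`.
#' @export
glance.schedule_fit <- function(x, ...) {
  tibble::tibble(kind = x$schedule$kind, gof = x$gof, gof_form = x$gof_form,
                 min_rate = min(x$schedule$rates),
                 max_rate = max(x$schedule$rates),
                 total_evals = sum(vapply(x$segments, function(s) s$evals,
                                          integer(1))))
}

#' Oxygen field as a tidy tibble
#'
#' @param x An `oxygen_field`.
#' @param ... Unused.
#' @return A tibble with `x_um`, `y_um`, `po2_mmHg`.
#' @export
as_tibble.oxygen_field <- function(x, ...) {
  xs <- seq(x$domain[1], x$domain[2], by = x$dx)
  ys <- seq(x$domain[3], x$domain[4], by = x$dx)
  tibble::tibble(x_um = rep(xs, each = length(ys)),
                 y_um = rep(ys, times = length(xs)),
                 po2_mmHg = as.vector(x$values))
}

#' Heatmap of an oxygen field
#'
#' Renders the nodal pO2 with the cyan-to-white ramp used in EPR oxygen maps
#' (cyan = hypoxic, white/yellow = well oxygenated).
#'
#' @param object An `oxygen_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxygen_field <- function(object, ...) {
  df <- as_tibble.oxygen_field(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$po2_mmHg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#00555a", "#00b7c2",
                                              "#ffe97f", "#ffffff"),
                                  name = "pO2 (mmHg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot a tissue layout
#'
#' Vessels in red, tumor cells in purple, stromal cells in pink, echoing
#' histology colors.
#'
#' @param object A `tissue_layout`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_layout <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   size = .data$radius_um,
                                   colour = .data$type)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(vessel = "#c0392b",
                                            tumor = "#6c3483",
                                            stromal = "#f5b7b1")) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Measured vs simulated series of a fitted schedule
#'
#' @param object A `schedule_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.schedule_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$target, series = "measured"),
    dplyr::mutate(object$simulated, series = "simulated"))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$po2_mmHg,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "mean pO2 (mmHg)",
                  subtitle = sprintf("%s schedule, GoF = %.3g",
                                     object$schedule$kind, object$gof))
}
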