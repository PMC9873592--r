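#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_density labs coord_equal facet_wrap geom_vline geom_hline
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods: cumulative maturity curve, posterior densities of
#' the growth coefficients, and utilization-distribution rasters.
#' `plot_captures()` maps detections over the board array.
#'
#' @param object fitted/derived object.
#' @param ... unused.
#' @name plethodem_plots
NULL

#' @rdname plethodem_plots
#' @export
autoplot.maturity_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$age, y = .data$prop_mature)) +
    geom_line() +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    geom_vline(xintercept = object$median_age, linetype = "dotted") +
    labs(x = "Age (years)", y = "Proportion mature",
         title = sprintf("Time to reach %.0f mm SVL (median %.2f yr)",
                         object$threshold, object$median_age))
}

#' @rdname plethodem_plots
#' @export
autoplot.growth_fit <- function(object, ...) {
  object$draws |>
    dplyr::select(dplyr::starts_with("k_")) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "group",
                        values_to = "k") |>
    dplyr::mutate(group = sub("^k_", "", .data$group)) |>
    ggplot(aes(x = .data$k, colour = .data$group)) +
    geom_density() +
    labs(x = expression(K ~ (yr^-1)), y = "Posterior density",
         colour = "plot x sex")
}

#' @rdname plethodem_plots
#' @export
autoplot.ud_grid <- function(object, ...) {
  df <- tidyr::expand_grid(y = object$y, x = object$x) |>
    dplyr::mutate(p = as.vector(object$p))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$p)) +
    geom_tile() +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)", fill = "mass")
}

#' @rdname plethodem_plots
#' @param captures capture tibble.
#' @param design a [study_design()].
#' @export
plot_captures <- function(captures, design) {
  ggplot(design$boards, aes(x = .data$x, y = .data$y)) +
    geom_point(shape = 3, colour = "grey50") +
    geom_point(data = captures,
               aes(x = .data$board_x, y = .data$board_y),
               alpha = 0.3, colour = "firebrick") +
    coord_equal() +
    facet_wrap(~primary) +
    labs(x = "x (m)", y = "y (m)")
}
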