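#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a lateral dose profile
#'
#' Dose versus lateral position on a logarithmic dose axis, which separates
#' the Gaussian core (a parabola in log scale) from the linear-exponential
#' halo tail (a straight line).
#'
#' @param object A [lateral_profile()].
#' @param log_dose Use a log10 dose axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pb_profile
#' @export
autoplot.pb_profile <- function(object, log_dose = TRUE, ...) {
  xlab <- if (profile_geometry(object) == "annular") {
    "radius (mm)"
  } else {
    "lateral position (mm)"
  }
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$position_mm, y = .data$dose)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = xlab, y = "relative dose",
      title = sprintf("%s, depth %.0f mm",
                      attr(object, "beam_label") %||% "profile",
                      attr(object, "depth_z_mm") %||% NA_real_)
    ) +
    ggplot2::theme_minimal()
  if (log_dose) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot an output-factor table
#'
#' Frame factors and field-size factors against the outer field size.
#'
#' @param object A [of_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pb_of_table
#' @export
autoplot.pb_of_table <- function(object, ...) {
  sizes <- standard_frames()$a_outer_cm
  tab <- tibble::as_tibble(object) |>
    dplyr::mutate(field_cm = sizes[.data$frame]) |>
    tidyr::pivot_longer(dplyr::any_of(c("ff", "fsf")),
                        names_to = "factor", values_to = "value") |>
    dplyr::mutate(factor = toupper(.data$factor))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$field_cm, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$factor), scales = "free_y") +
    ggplot2::labs(x = "field size (cm)", y = "factor") +
    ggplot2::theme_minimal()
}

#' Plot a scattering-growth curve
#'
#' @param object A [sigma_sc_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pb_sc_curve
#' @export
autoplot.pb_sc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth_z_mm, y = .data$sigma_sc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "depth (mm)", y = expression(sigma[sc] ~ "(mm)")) +
    ggplot2::theme_minimal()
}
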