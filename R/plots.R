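#' Plot a belt height profile
#'
#' Line plot of the per-bin mean belt height against the bearing around the
#' trimer axis, optionally with coloured bars along the bottom marking which
#' protomer domain (scaffold/transport) the belt covers at each bearing —
#' the standard way of displaying nanodisc-belt buckling around a membrane
#' protein.
#'
#' @param object A `belt_profile` from [belt_height_profile()].
#' @param sectors Optional sector annotation from [annotate_sectors()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.belt_profile <- function(object, sectors = NULL, ...) {
  df <- as_tibble(object) %>% filter(.data$n_atoms > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_deg,
                                        y = .data$mean_height_A)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 360, 60),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "perimeter position (deg)",
                  y = "belt height (Å)") +
    ggplot2::theme_minimal()
  if ("chain" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$chain)
  }
  if (!is.null(sectors)) {
    bar_y <- min(df$mean_height_A, na.rm = TRUE) -
      0.08 * diff(range(df$mean_height_A, na.rm = TRUE) + c(0, 1e-9))
    sec <- sectors %>% filter(.data$label != "none")
    p <- p + ggplot2::geom_rect(
      data = sec,
      ggplot2::aes(xmin = .data$start_deg, xmax = .data$end_deg,
                   fill = .data$label),
      ymin = bar_y - 0.4, ymax = bar_y + 0.4,
      inherit.aes = FALSE) +
      ggplot2::labs(fill = "covered domain")
  }
  p
}

#' Plot the protomer states of an analysed structure
#'
#' Elevator coordinate per protomer, coloured by position label and shaped
#' by gate state — a compact view of the trimer's (a)symmetry.
#'
#' @param object A `transporter_analysis` from [analyze_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transporter_analysis <- function(object, ...) {
  ggplot2::ggplot(object$protomers,
                  ggplot2::aes(x = .data$chain, y = .data$elevator_coordinate_A,
                               colour = .data$position_label,
                               shape = .data$gate_label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "protomer", y = "elevator coordinate (Å)",
                  colour = "position", shape = "gate",
                  title = object$identifier) +
    ggplot2::theme_minimal()
}

#' Plot a trimer state distribution
#'
#' @param object A `state_distribution` from [trimer_state_distribution()]
#'   (binomial form).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_distribution <- function(object, ...) {
  if (!"k" %in% names(object)) {
    abort("autoplot is defined for the binomial (scalar-p) distribution")
  }
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = factor(.data$k),
                                                  y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "occupied protomers per trimer", y = "probability") +
    ggplot2::theme_minimal()
}
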