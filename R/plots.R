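# ggplot2 views of the main result types

#' Tissue plot of a section's cells
#'
#' @param section a `retina_section`, or a cell tibble with `x`, `y` and a
#'   label column.
#' @param colour_by column used for the point colour (default `major_type`).
#' @return a ggplot.
#' @export
plot_section <- function(section, colour_by = "major_type") {
  cells <- if (inherits(section, "retina_section")) section$cells else section
  check_columns(cells, c("x", "y"), "`section`")
  ggplot2::ggplot(cells, ggplot2::aes(.data$x, .data$y,
                                      colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' Boxplot of per-subtype laminar positions
#'
#' @param x a [summarize_laminar_positions()] result.
#' @param ... unused.
#' @return a ggplot (0 = apical boundary, 1 = basal boundary by the default
#'   depth convention).
#' @export
plot_laminar_positions <- function(x, ...) {
  stopifnot(inherits(x, "laminar_summary"))
  df <- x$summary |> arrange(.data$median)
  df$subtype <- factor(df$subtype, levels = df$subtype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subtype)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity", fill = "grey85"
    ) +
    ggplot2::labs(x = NULL, y = "normalized laminar depth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.laminar_summary <- function(object, ...) plot_laminar_positions(object, ...)

#' Bar plot of per-subtype displacement proportions
#'
#' @param x a [displacement_test()] result.
#' @param ... unused.
#' @return a ggplot; significant subtypes are highlighted.
#' @export
plot_displacement <- function(x, ...) {
  stopifnot(inherits(x, "displacement_test"))
  df <- tidy(x) |> arrange(desc(.data$observed_prop))
  df$subtype <- factor(df$subtype, levels = df$subtype)
  ggplot2::ggplot(df, ggplot2::aes(.data$subtype, .data$observed_prop,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "proportion of cells in the GCL",
                  fill = sprintf("p < %.2g", x$alpha)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.displacement_test <- function(object, ...) plot_displacement(object, ...)

#' Plot boundary chains over the point cloud
#'
#' @param x a [classify_boundary_edges()] result.
#' @param points optional background points (matrix or data frame).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_boundaries <- function(x, points = NULL, ...) {
  stopifnot(inherits(x, "boundary_chains"))
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    m <- as_xy_matrix(points)
    p <- p + ggplot2::geom_point(
      data = tibble(x = m[, 1], y = m[, 2]),
      ggplot2::aes(.data$x, .data$y), size = 0.2, colour = "grey70")
  }
  seg <- x$edges |>
    mutate(role = .data$role)
  pts <- attr(x, "points")
  p +
    ggplot2::geom_point(
      data = tibble(x = seg$mid_x, y = seg$mid_y, role = seg$role),
      ggplot2::aes(.data$x, .data$y, colour = .data$role), size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "boundary") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.boundary_chains <- function(object, ...) plot_boundaries(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
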