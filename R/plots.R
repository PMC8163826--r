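#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a lattice graph into its unit table
#'
#' @param x A [lattice_graph].
#' @param ... Unused.
#' @return The unit particle table (tibble).
#' @export
tidy.lattice_graph <- function(x, ...) x$units

#' One-row lattice summary
#'
#' @param x A [lattice_graph].
#' @param ... Unused.
#' @return Tibble with unit/edge counts and topology flags.
#' @export
glance.lattice_graph <- function(x, ...) {
  tibble(n_units = nrow(x$units),
         n_pentamers = sum(x$units$unit_type == "pentamer_C5"),
         n_hexamers = sum(x$units$unit_type != "pentamer_C5"),
         n_edges = nrow(x$edges),
         closed = isTRUE(x$closed),
         mean_spacing = if (nrow(x$edges)) mean(x$edges$distance) else NA_real_)
}

#' @export
tidy.fsc_curve <- function(x, ...) tibble(freq = x$freq, fsc = x$fsc,
                                          n_voxels = x$n_voxels)

#' One-row FSC summary (resolution at 0.143)
#' @param x An [fsc] curve.
#' @param threshold FSC threshold.
#' @param ... Unused.
#' @export
glance.fsc_curve <- function(x, threshold = 0.143, ...) {
  r <- resolution_at(x, threshold)
  tibble(resolution = as.numeric(r),
         nyquist_limited = isTRUE(attr(r, "nyquist_limited")),
         threshold = threshold)
}

#' Plot an FSC curve
#'
#' @param object An [fsc] curve.
#' @param threshold Threshold line to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fsc_curve <- function(object, threshold = 0.143, ...) {
  ggplot2::ggplot(tidy.fsc_curve(object),
                  ggplot2::aes(x = .data$freq, y = .data$fsc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "spatial frequency (1/Å)", y = "FSC") +
    ggplot2::theme_minimal()
}

#' Plot a lattice graph projection
#'
#' 2D projection of the unit positions with neighbour edges; pentamers and
#' hexamers are distinguished by colour.
#'
#' @param object A [lattice_graph].
#' @param axes Which coordinates to plot (default x/y).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lattice_graph <- function(object, axes = c("x", "y"), ...) {
  u <- object$units
  e <- object$edges
  seg <- tibble(x0 = u[[axes[1]]][e$from], y0 = u[[axes[2]]][e$from],
                x1 = u[[axes[1]]][e$to], y1 = u[[axes[2]]][e$to])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70") +
    ggplot2::geom_point(data = u,
                        ggplot2::aes(x = .data[[axes[1]]],
                                     y = .data[[axes[2]]],
                                     colour = .data$unit_type), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(axes[1], "(voxels)"),
                  y = paste(axes[2], "(voxels)"), colour = "unit type") +
    ggplot2::theme_minimal()
}

#' Bar chart of the classification group census
#'
#' @param classified Output of [classify_edges].
#' @return A ggplot.
#' @export
plot_class_census <- function(classified) {
  ggplot2::ggplot(classified, ggplot2::aes(x = factor(.data$group))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "context group", y = "unit pairs") +
    ggplot2::theme_minimal()
}
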