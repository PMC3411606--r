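# ggplot2 views of the main result types.

#' Plot a 2D conformational density
#'
#' Filled-raster view of the kernel density estimate over (RMSD, Rg).
#'
#' @param object A `kde2d_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kde2d_result <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$x), j = seq_along(object$y))
  df <- mutate(df, rmsd = object$x[.data$i], rg = object$y[.data$j],
               density = object$z[cbind(.data$i, .data$j)])
  ggplot2::ggplot(df, ggplot2::aes(.data$rmsd, .data$rg, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "RMSD from reference (Å)",
                  y = "Radius of gyration (Å)", fill = "PDF") +
    ggplot2::theme_minimal()
}

#' Plot a state model
#'
#' The density surface with detected modes marked and labelled by state.
#'
#' @param object A `state_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.state_model <- function(object, ...) {
  autoplot(object$kde) +
    ggplot2::geom_point(data = object$modes,
                        ggplot2::aes(.data$rmsd, .data$rg),
                        inherit.aes = FALSE, color = "white", shape = 4, size = 2) +
    ggplot2::geom_text(data = object$modes,
                       ggplot2::aes(.data$rmsd, .data$rg,
                                    label = .data$state),
                       inherit.aes = FALSE, color = "white", vjust = -0.8)
}

#' Plot an electron density profile
#'
#' Mean density per slab with a +/- 1 sd ribbon (across frames).
#'
#' @param object A `density_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$z_center, .data$density))
  if (!all(is.na(df$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$density - .data$sd,
                   ymax = .data$density + .data$sd),
      fill = "grey80")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "z (Å)",
                  y = expression("Electron density (e/Å"^3 * ")"),
                  title = attr(object, "selection_label")) +
    ggplot2::theme_minimal()
}

#' Plot a helicity trace
#'
#' @param trace A tibble from [helicity_trace()].
#' @return A ggplot of percent folded per frame.
#' @export
plot_helicity_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(.data$frame, .data$percent_folded)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "Frame", y = "% folded (backbone H-bonds)") +
    ggplot2::theme_minimal()
}
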