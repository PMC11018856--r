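#' Plot lattice disorder in the ac plane
#'
#' Scatter of inverse-transformed chain displacements projected onto the
#' unit a/c cell directions; an undistorted lattice collapses to the
#' origin.
#'
#' @param displacements tibble from [inverse_lattice_transform()].
#' @return A ggplot.
#' @export
plot_lattice_disorder <- function(displacements) {
  ggplot2::ggplot(displacements,
                  ggplot2::aes(x = .data$ac_u, y = .data$ac_v)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "displacement along a (Å)",
                  y = "displacement along c (Å)",
                  title = "Lattice disorder (ac projection)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bfactor_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$b)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "residue", y = "B (Å²)",
                  title = sprintf("B-factors (%s)", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.covariance_decay <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$center, y = .data$mean_cov)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "distance (Å)", y = "covariance (Å²)",
                  subtitle = sprintf("A = %.3g Å², decay length = %.3g Å",
                                     object$amplitude, object$decay_length)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.projection_model <- function(object, ...) {
  sc <- object$scores
  axes <- if (object$kind == "pca") c("PC1", "PC2") else c("LD1", "LD2")
  axes <- intersect(axes, names(sc))
  if (length(axes) == 1) sc$.y <- 0
  p <- ggplot2::ggplot(sc, ggplot2::aes(
    x = .data[[axes[1]]],
    y = if (length(axes) > 1) .data[[axes[2]]] else .data$.y))
  if ("group" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                                 alpha = 0.6, size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  p + ggplot2::labs(y = if (length(axes) > 1) axes[2] else "") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$p)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p - .data$se,
                                        ymax = .data$p + .data$se),
                           width = 0) +
    ggplot2::labs(x = "distance (Å)", y = "p(x)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.free_energy_profile <- function(object, ...) {
  sub <- object[is.finite(object$g_kt), ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$center, y = .data$g_kt)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$g_kt - .data$g_se,
                                      ymax = .data$g_kt + .data$g_se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Å)",
                  y = expression(G ~ (k[B] * T))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.deviation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue,
                                       y = .data$deviation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "mean Cα deviation (Å)") +
    ggplot2::theme_minimal()
}
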