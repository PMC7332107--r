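#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_path
#'   geom_errorbar geom_col labs theme_minimal scale_linetype_manual
#'   geom_hline facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a polarity model trajectory
#'
#' Polar fractions of each species over time; solid lines for pole 1,
#' dashed for pole 2.
#'
#' @param object A `polarity_trajectory` from [simulate_polarity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polarity_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "pool", values_to = "fraction")
  long$species <- c(A = "MglA", B = "MglB", R = "RomR")[substr(long$pool, 1, 1)]
  long$pole <- paste("pole", substr(long$pool, 2, 2))
  ggplot(long, aes(x = .data$time, y = .data$fraction,
                   colour = .data$species, linetype = .data$pole)) +
    geom_line() +
    labs(x = "time (min)", y = "polar fraction",
         colour = NULL, linetype = NULL) +
    theme_minimal()
}

#' Plot a bifurcation scan
#'
#' For a one-dimensional scan (single `d_AB`), the RomR polar fractions at
#' both poles versus `K` (the branch diagram); for a grid, the steady-state
#' RomR asymmetry as a raster over `K` and `d_AB`.
#'
#' @param object A `bifurcation_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  if (length(unique(object$d_AB)) == 1) {
    long <- tidyr::pivot_longer(object, c("R1", "R2"),
                                names_to = "pole", values_to = "fraction")
    ggplot(long, aes(x = .data$K, y = .data$fraction,
                     colour = .data$pole)) +
      geom_line() + geom_point(size = 0.8) +
      ggplot2::scale_x_log10() +
      labs(x = "MglA suppression constant K", y = "RomR polar fraction",
           colour = NULL) +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data$K, y = .data$d_AB,
                       fill = .data$omega_R)) +
      ggplot2::geom_raster() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      labs(x = "K", y = "d_AB", fill = expression(omega[R])) +
      theme_minimal()
  }
}

#' Plot a strain summary
#'
#' Single-cell polar fractions with the strain mean and the dispersion
#' ellipse axes (eigenvectors of the polar-fraction covariance matrix,
#' scaled by the square roots of the eigenvalues).
#'
#' @param object A `strain_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strain_summary <- function(object, ...) {
  m <- object$mean_poles
  axes <- do.call(rbind, lapply(1:2, function(k) {
    v <- object$ellipse_axes[, k] * object$ellipse_lengths[k]
    tibble(axis = k, x = m[1] - v[1], y = m[2] - v[2],
           xend = m[1] + v[1], yend = m[2] + v[2])
  }))
  ggplot(object$records, aes(x = .data$P1, y = .data$P2)) +
    geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_segment(data = axes,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend),
                          inherit.aes = FALSE, colour = "red") +
    ggplot2::annotate("point", x = m[1], y = m[2], colour = "red",
                      size = 2) +
    labs(x = "polar fraction 1", y = "polar fraction 2") +
    theme_minimal()
}

#' Plot a binned induction curve
#'
#' Per-bin mean polar fractions (error bars: one standard deviation)
#' against fluorescence concentration.
#'
#' @param object An `induction_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.induction_analysis <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object$bins, concentration = .data$concentration,
                     pole = "pole 1", mean = .data$P1_mean,
                     sd = .data$P1_sd),
    dplyr::transmute(object$bins, concentration = .data$concentration,
                     pole = "pole 2", mean = .data$P2_mean,
                     sd = .data$P2_sd))
  ggplot(long, aes(x = .data$concentration, y = .data$mean,
                   colour = .data$pole)) +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0) +
    geom_point() + geom_line() +
    labs(x = "fluorescence concentration", y = "polar fraction",
         colour = NULL) +
    theme_minimal()
}

#' Plot an autocorrelation series
#'
#' @param object An `autocorr_series` from [polar_autocorrelation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.autocorr_series <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_minutes, y = .data$C)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_line() + geom_point() +
    labs(x = "lag (min)", y = "autocorrelation C") +
    theme_minimal()
}
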