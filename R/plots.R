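# ggplot2 visualisations for each result type.

#' Plot a state comparison
#'
#' Scatter of (cos theta, delta_n) per resonance, colored by
#' classification, with the fully closed on-pathway point (1, 1) marked.
#'
#' @param object A `state_comparison` from [compare_states()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.state_comparison <- function(object, ...) {
  rows <- dplyr::filter(object$rows, !is.na(.data$cos_theta),
                        !is.na(.data$delta_n))
  ggplot2::ggplot(rows, ggplot2::aes(.data$cos_theta, .data$delta_n,
                                     colour = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = 1, y = 1, shape = 3, size = 3) +
    ggplot2::labs(
      x = "cos θ", y = "Δδn",
      title = paste0(object$test_state, " vs ", object$reference_open,
                     " → ", object$reference_closed),
      subtitle = sprintf("RMSD_1.0 = %.3f", object$rmsd_global)) +
    ggplot2::theme_minimal()
}

#' Plot closure per subdomain
#'
#' Bar chart of RMSD from full closure per subdomain.
#'
#' @param comparison A `state_comparison`.
#' @return A ggplot object.
#' @export
plot_subdomain_rmsd <- function(comparison) {
  ggplot2::ggplot(comparison$rmsd_by_subdomain,
                  ggplot2::aes(.data$subdomain, .data$rmsd)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "RMSD_1.0") +
    ggplot2::theme_minimal()
}

plot_fit_curve <- function(times, observed, fitted, xlab, ylab) {
  d <- tibble(x = times, observed = observed, fitted = fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.state_comparison
#' @exportS3Method ggplot2::autoplot
autoplot.burst_fit <- function(object, ...) {
  plot_fit_curve(object$times, object$product, object$fitted,
                 "time (s)", "product (nM)")
}

#' @rdname autoplot.state_comparison
#' @exportS3Method ggplot2::autoplot
autoplot.single_exp_fit <- function(object, ...) {
  plot_fit_curve(object$times, object$product, object$fitted,
                 "time (s)", "product (nM)")
}

#' @rdname autoplot.state_comparison
#' @exportS3Method ggplot2::autoplot
autoplot.saturation_fit <- function(object, ...) {
  plot_fit_curve(object$dNTP, object$k_obs, object$fitted,
                 "[dNTP] (µM)", expression(k[obs] ~ (s^-1)))
}

#' Plot a dispersion panel fit
#'
#' R2_eff versus refocusing frequency for each residue, with flexible
#' residues highlighted.
#'
#' @param data Long dispersion tibble (`residue`, `nu_cpmg`, `R2_eff`).
#' @param fits Per-residue fit tibble from [fit_dispersion_panel()].
#' @return A ggplot object.
#' @export
plot_dispersion_panel <- function(data, fits) {
  d <- dplyr::left_join(data, fits[c("residue", "flexible")], by = "residue")
  ggplot2::ggplot(d, ggplot2::aes(.data$nu_cpmg, .data$R2_eff,
                                  group = .data$residue,
                                  colour = .data$flexible)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = expression(nu[CPMG] ~ (s^-1)),
                  y = expression(R[2 * eff] ~ (s^-1))) +
    ggplot2::theme_minimal()
}
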