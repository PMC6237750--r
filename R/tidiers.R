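# tidy()/glance() methods for fitted objects.

#' @exportS3Method generics::tidy
tidy.state_comparison <- function(x, ...) x$rows

#' @exportS3Method generics::glance
glance.state_comparison <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.burst_fit <- function(x, ...) {
  tibble(term = c("E_app", "k_obs", "k_ss"),
         estimate = c(x$E_app, x$k_obs, x$k_ss))
}

#' @exportS3Method generics::glance
glance.burst_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         degenerate = x$degenerate, form = x$form)
}

#' @exportS3Method generics::tidy
tidy.single_exp_fit <- function(x, ...) {
  tibble(term = c("A", "k_obs"), estimate = c(x$A, x$k_obs))
}

#' @exportS3Method generics::glance
glance.single_exp_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.saturation_fit <- function(x, ...) {
  tibble(term = c("k_pol", "K_d_dNTP"), estimate = c(x$k_pol, x$K_d_dNTP))
}

#' @exportS3Method generics::glance
glance.saturation_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         ill_conditioned = x$ill_conditioned)
}

#' @exportS3Method generics::tidy
tidy.global_fit <- function(x, ...) {
  tibble(term = names(x$rates), estimate = unname(x$rates),
         free = names(x$rates) %in% names(x$free))
}

#' @exportS3Method generics::glance
glance.global_fit <- function(x, ...) {
  tibble(residual_norm = x$residual_norm, converged = x$converged,
         ill_conditioned = x$ill_conditioned, n_free = length(x$free))
}

#' @exportS3Method generics::tidy
tidy.trap_fit <- function(x, ...) {
  dplyr::bind_cols(x$assignment,
                   tibble(amplitude = unname(x$amplitudes)))
}

#' @exportS3Method generics::glance
glance.trap_fit <- function(x, ...) {
  tibble(n_exp_best = x$n_exp_best, ambiguous = x$ambiguous,
         residual_norm = x$residual_norm, offset = x$offset)
}

#' @exportS3Method generics::tidy
tidy.dispersion_fit <- function(x, ...) {
  tibble(term = c("R2_0", "R_ex", "k_ex"),
         estimate = c(x$R2_0, x$R_ex, x$k_ex))
}

#' @exportS3Method generics::glance
glance.dispersion_fit <- function(x, ...) {
  tibble(model_choice = x$model_choice, flexible = x$flexible,
         p_value = x$p_value, rss_flat = x$rss_flat, rss_disp = x$rss_disp)
}

#' @exportS3Method base::print
print.polscape_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}
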