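# CPMG relaxation dispersion: fast-exchange model, per-residue fitting and
# the millisecond-flexibility criterion.

#' Fast-exchange CPMG dispersion model
#'
#' Effective transverse relaxation rate as a function of the refocusing
#' interval \eqn{\tau_{cp}}:
#' \deqn{R_2(1/\tau_{cp}) = R_2^0 + R_{ex}\left[1 -
#'   \frac{2\tanh(k_{ex}\tau_{cp}/2)}{k_{ex}\tau_{cp}}\right].}
#' As \eqn{\tau_{cp}\to 0} (fast pulsing) exchange is refocused and
#' \eqn{R_2\to R_2^0}; as \eqn{\tau_{cp}\to\infty} the full exchange
#' contribution appears, \eqn{R_2\to R_2^0 + R_{ex}}.
#'
#' @param nu_cpmg Refocusing frequency \eqn{1/\tau_{cp}} (s^-1), > 0.
#' @param R2_0 Exchange-free relaxation rate (s^-1).
#' @param R_ex Exchange contribution (s^-1), >= 0.
#' @param k_ex Exchange rate between the two sites (s^-1), > 0.
#' @return R2 effective (s^-1).
#' @export
r2_model <- function(nu_cpmg, R2_0, R_ex, k_ex) {
  if (any(nu_cpmg <= 0)) abort("`nu_cpmg` must be > 0.")
  if (R2_0 <= 0 || R_ex < 0 || k_ex <= 0) {
    abort("Require R2_0 > 0, R_ex >= 0, k_ex > 0.")
  }
  x <- k_ex / (2 * nu_cpmg)  # = k_ex * tau_cp / 2
  R2_0 + R_ex * (1 - tanh(x) / x)
}

#' Exchange contribution from populations and shift difference
#'
#' Fast-exchange limit \eqn{R_{ex} = p_a p_b \Delta\omega^2 / k_{ex}},
#' with equilibrium populations `p_a + p_b = 1` and the chemical-shift
#' difference between the sites in angular frequency units.
#'
#' @param p_a,p_b Equilibrium site populations (sum to 1, both > 0).
#' @param delta_omega Shift difference between sites (rad s^-1).
#' @param k_ex Exchange rate (s^-1), > 0.
#' @return R_ex in s^-1.
#' @export
rex_from_populations <- function(p_a, p_b, delta_omega, k_ex) {
  if (any(abs(p_a + p_b - 1) > 1e-8)) abort("Populations must sum to 1.")
  if (any(p_a <= 0) || any(p_b <= 0) || any(k_ex <= 0)) {
    abort("Populations and k_ex must be > 0.")
  }
  p_a * p_b * delta_omega^2 / k_ex
}

#' Fit one dispersion curve and decide flexibility
#'
#' Fits both a flat model (a single `R2_0`, no exchange) and the
#' fast-exchange dispersion model, and prefers the dispersive model when a
#' nested-model F-test rejects the flat one at `alpha` (AIC available as
#' an alternative criterion). A residue is called flexible when the
#' dispersive model is preferred and the fitted `R_ex` exceeds
#' `rex_cutoff` (2 s^-1).
#'
#' @param nu_cpmg Refocusing frequencies (s^-1), at least 5.
#' @param R2_eff Measured effective relaxation rates (s^-1).
#' @param sigma Optional per-point uncertainties (s^-1) used as weights.
#' @param alpha Test level for model preference (default 0.05).
#' @param criterion `"ftest"` (default) or `"aic"`.
#' @param rex_cutoff Flexibility threshold on R_ex (s^-1).
#' @return Object of class `dispersion_fit`: `R2_0`, `R_ex`, `k_ex`,
#'   `model_choice` (`"flat"` or `"dispersive"`), `flexible`, `p_value`,
#'   `rss_flat`, `rss_disp`.
#' @export
fit_dispersion <- function(nu_cpmg, R2_eff, sigma = NULL, alpha = 0.05,
                           criterion = c("ftest", "aic"), rex_cutoff = 2) {
  criterion <- match.arg(criterion)
  if (length(nu_cpmg) < 5L) abort("Need at least 5 dispersion points.")
  if (length(nu_cpmg) != length(R2_eff)) {
    abort("`nu_cpmg` and `R2_eff` must have equal length.")
  }
  check_finite(R2_eff, "R2_eff")
  w <- if (is.null(sigma)) rep(1, length(nu_cpmg)) else 1 / sigma
  n <- length(nu_cpmg)

  # flat model: weighted mean
  r2_flat <- sum(w^2 * R2_eff) / sum(w^2)
  rss_flat <- sum((w * (R2_eff - r2_flat))^2)

  resid_fn <- function(p) {
    w * (R2_eff - r2_model(nu_cpmg, exp(p[1]), exp(p[2]), exp(p[3])))
  }
  best <- NULL
  kex_starts <- c(2, 10, 50) * stats::median(nu_cpmg)
  rex0 <- max(max(R2_eff) - min(R2_eff), 0.1)
  for (kex0 in kex_starts) {
    p0 <- log(c(max(min(R2_eff), 0.1), rex0, kex0))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    warn("Dispersive fit failed to converge; reporting the flat model.")
    return(structure(
      list(R2_0 = r2_flat, R_ex = 0, k_ex = NA_real_, model_choice = "flat",
           flexible = FALSE, p_value = NA_real_, rss_flat = rss_flat,
           rss_disp = NA_real_),
      class = "dispersion_fit"))
  }
  p <- exp(best$par)
  rss_disp <- best$deviance
  if (criterion == "ftest") {
    # nested: flat (1 parameter) inside dispersive (3 parameters)
    fstat <- ((rss_flat - rss_disp) / 2) / (rss_disp / (n - 3))
    p_value <- if (fstat > 0) pf(fstat, 2, n - 3, lower.tail = FALSE) else 1
    dispersive <- is.finite(p_value) && p_value < alpha
  } else {
    aic_flat <- n * log(rss_flat / n) + 2 * 1
    aic_disp <- n * log(rss_disp / n) + 2 * 3
    p_value <- NA_real_
    dispersive <- aic_disp < aic_flat
  }
  model_choice <- if (dispersive) "dispersive" else "flat"
  structure(
    list(R2_0 = if (dispersive) p[1] else r2_flat,
         R_ex = if (dispersive) p[2] else 0,
         k_ex = if (dispersive) p[3] else NA_real_,
         model_choice = model_choice,
         flexible = dispersive && p[2] > rex_cutoff,
         p_value = p_value, rss_flat = rss_flat, rss_disp = rss_disp),
    class = "dispersion_fit"
  )
}

#' @importFrom stats pf
NULL

#' Fit a panel of dispersion curves
#'
#' Applies [fit_dispersion()] per residue over a long table of dispersion
#' points.
#'
#' @param data Tibble with columns `residue` (or any key), `nu_cpmg`,
#'   `R2_eff`, optional `sigma`.
#' @param ... Passed to [fit_dispersion()].
#' @return Tibble with one row per residue: fitted parameters,
#'   `model_choice`, `flexible`, `p_value`.
#' @export
fit_dispersion_panel <- function(data, ...) {
  data |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_dispersion(d$nu_cpmg, d$R2_eff,
                          sigma = if ("sigma" %in% names(d)) d$sigma else NULL,
                          ...)
      tibble(R2_0 = f$R2_0, R_ex = f$R_ex, k_ex = f$k_ex,
             model_choice = f$model_choice, flexible = f$flexible,
             p_value = f$p_value)
    }) |>
    dplyr::ungroup()
}

#' Count flexible residues in a panel
#'
#' @param fits Tibble from [fit_dispersion_panel()] (or any data frame
#'   with a logical `flexible` column), or a list of `dispersion_fit`
#'   objects.
#' @return Integer count of residues with `flexible = TRUE`.
#' @export
count_flexible <- function(fits) {
  if (is.data.frame(fits)) return(sum(fits$flexible, na.rm = TRUE))
  sum(vapply(fits, function(f) isTRUE(f$flexible), logical(1)))
}
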