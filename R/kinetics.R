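# Pre-steady-state kinetics: biphasic burst and single-turnover fits, and
# the discrimination / efficiency / fidelity arithmetic for nucleotide
# incorporation.

#' Biphasic burst model for product formation
#'
#' Product concentration after mixing enzyme-DNA with dNTP, with a fast
#' first-turnover (burst) phase followed by a linear steady-state phase.
#' The `"standard"` form is
#' \deqn{[P](t) = E_{app}\left[\left(\frac{k_{obs}}{k_{obs}+k_{ss}}\right)^2
#'   (1 - e^{-(k_{obs}+k_{ss})t}) +
#'   \frac{k_{obs} k_{ss}}{k_{obs}+k_{ss}} t\right],}
#' which has the correct amplitude limit \eqn{E_{app}} as
#' \eqn{k_{ss}\to 0}. The `"as_printed"` form replaces the squared ratio
#' with \eqn{k_{obs}/(k_{obs}+k_{ss})^2} (a transcription variant found in
#' print, dimensionally inconsistent; kept for literal reproduction).
#'
#' @param t Time (s).
#' @param E_app Burst amplitude (active-site concentration, nM).
#' @param k_obs Observed burst rate (s^-1).
#' @param k_ss Steady-state rate (s^-1).
#' @param form `"standard"` (default) or `"as_printed"`.
#' @return Product concentration, same units as `E_app`.
#' @export
burst_model <- function(t, E_app, k_obs, k_ss,
                        form = c("standard", "as_printed")) {
  form <- match.arg(form)
  check_finite(t, "t")
  if (k_obs < 0 || k_ss < 0) abort("Rates must be non-negative.")
  ktot <- k_obs + k_ss
  amp <- if (form == "standard") (k_obs / ktot)^2 else k_obs / ktot^2
  E_app * (amp * (1 - exp(-ktot * t)) + (k_obs * k_ss / ktot) * t)
}

#' Fit a biphasic burst progress curve
#'
#' Nonlinear least-squares fit of [burst_model()] to a product time
#' course, with multi-start initialization over log-spaced rate grids to
#' avoid local minima.
#'
#' @param times,product Time (s) and product concentration vectors.
#' @param form Passed to [burst_model()].
#' @param weights Optional weights (e.g. `1/sigma^2`); default unweighted.
#' @return Object of class `burst_fit`: list with `E_app`, `k_obs`,
#'   `k_ss`, `residual_norm`, `fitted`, `converged`, `degenerate` (set
#'   when the curve shows no resolvable burst phase and `k_obs` is
#'   unbounded by the data).
#' @export
fit_burst <- function(times, product, form = c("standard", "as_printed"),
                      weights = NULL) {
  form <- match.arg(form)
  check_progress_curve(times, product, min_points = 6L)
  w <- sqrt(weights %||% rep(1, length(times)))
  resid_fn <- function(p) {
    w * (product - burst_model(times, exp(p[1]), exp(p[2]), exp(p[3]), form))
  }
  span <- diff(range(times))
  starts <- expand.grid(
    k_obs = 10^seq(-1, 2, length.out = 4) / span,
    k_ss = 10^seq(-2, 1, length.out = 4) / span
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(c(max(product) * 0.8 + 1e-12, starts$k_obs[i], starts$k_ss[i]))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("Burst fit failed to converge from any start.")
  p <- exp(best$par)
  # no resolvable burst: exponential phase faster than sampling, burst
  # amplitude negligible against the linear phase, or the two phases have
  # collapsed onto a straight line
  burst_amp <- p[1] * (p[2] / (p[2] + p[3]))^2
  degenerate <- p[2] > 50 / min(diff(times)) ||
    burst_amp < 0.05 * diff(range(product)) ||
    abs(p[2] - p[3]) / p[2] < 1e-3
  structure(
    list(E_app = p[1], k_obs = p[2], k_ss = p[3],
         residual_norm = sqrt(best$deviance), form = form,
         fitted = burst_model(times, p[1], p[2], p[3], form),
         times = times, product = product,
         converged = best$info %in% 1:4, degenerate = degenerate),
    class = c("burst_fit", "polscape_fit")
  )
}

#' Fit a single-exponential progress curve
#'
#' Fits \eqn{[P](t) = A (1 - e^{-k_{obs} t})} to a single-turnover time
#' course.
#'
#' @inheritParams fit_burst
#' @return Object of class `single_exp_fit`: list with `A`, `k_obs`,
#'   `residual_norm`, `fitted`.
#' @export
fit_single_exponential <- function(times, product, weights = NULL) {
  check_progress_curve(times, product, min_points = 4L)
  if (max(abs(product)) < .Machine$double.eps^0.5) {
    abort("Progress curve is identically zero; no exponential to fit.")
  }
  w <- sqrt(weights %||% rep(1, length(times)))
  resid_fn <- function(p) {
    w * (product - exp(p[1]) * (1 - exp(-exp(p[2]) * times)))
  }
  span <- diff(range(times))
  best <- NULL
  for (k0 in 10^seq(-1, 2, length.out = 6) / span) {
    fit <- tryCatch(
      minpack.lm::nls.lm(log(c(max(product) + 1e-12, k0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("Single-exponential fit failed to converge.")
  p <- exp(best$par)
  structure(
    list(A = p[1], k_obs = p[2], residual_norm = sqrt(best$deviance),
         fitted = p[1] * (1 - exp(-p[2] * times)),
         times = times, product = product, converged = best$info %in% 1:4),
    class = c("single_exp_fit", "polscape_fit")
  )
}

#' Fit the hyperbolic dNTP saturation curve
#'
#' Fits \eqn{k_{obs} = k_{pol} [dNTP] / (K_d + [dNTP])} to observed rates
#' across a dNTP titration, yielding the maximum polymerization rate
#' `k_pol` (s^-1) and the apparent nucleotide dissociation constant
#' `K_d_dNTP` (uM).
#'
#' @param dNTP Nucleotide concentrations (uM).
#' @param k_obs Observed single-turnover rates (s^-1).
#' @param weights Optional weights.
#' @return Object of class `saturation_fit`: list with `k_pol`,
#'   `K_d_dNTP`, `residual_norm`, `fitted`, `ill_conditioned` (flagged
#'   when the titration does not span `K_d`).
#' @export
fit_saturation <- function(dNTP, k_obs, weights = NULL) {
  if (length(dNTP) < 3L) abort("Need at least 3 dNTP concentrations.")
  if (any(dNTP <= 0)) abort("dNTP concentrations must be > 0.")
  check_finite(k_obs, "k_obs")
  w <- sqrt(weights %||% rep(1, length(dNTP)))
  resid_fn <- function(p) {
    w * (k_obs - exp(p[1]) * dNTP / (exp(p[2]) + dNTP))
  }
  best <- NULL
  for (kd0 in 10^seq(log10(min(dNTP)), log10(max(dNTP)), length.out = 5)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(log(c(max(k_obs) + 1e-12, kd0)), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("Saturation fit failed to converge.")
  p <- exp(best$par)
  ill <- p[2] < min(dNTP) / 10 || p[2] > max(dNTP) * 10
  if (ill) {
    warn("Titration does not span K_d; the saturation fit is ill-conditioned.")
  }
  structure(
    list(k_pol = p[1], K_d_dNTP = p[2], residual_norm = sqrt(best$deviance),
         fitted = p[1] * dNTP / (p[2] + dNTP), dNTP = dNTP, k_obs = k_obs,
         converged = best$info %in% 1:4, ill_conditioned = ill),
    class = c("saturation_fit", "polscape_fit")
  )
}

round_sig <- function(x, digits = 2) signif(x, digits)

#' Discrimination, efficiency and fidelity for one base pair
#'
#' From single-turnover parameters for the correct and incorrect incoming
#' nucleotide at one templating base, computes: discrimination of k_pol
#' (correct/incorrect), discrimination of K_d (incorrect/correct),
#' catalytic efficiencies k_pol/K_d (uM^-1 s^-1), and
#' fidelity = (correct efficiency + incorrect efficiency) / incorrect
#' efficiency. With `rounding = "as_printed"` the efficiencies are rounded
#' to 2 significant figures before the fidelity quotient, matching how
#' published tables are typically assembled; `"none"` keeps full precision.
#'
#' @param correct,incorrect Named lists or vectors with `k_pol` (s^-1) and
#'   `K_d` (uM).
#' @param rounding `"as_printed"` (default) or `"none"`.
#' @return One-row tibble with columns `D_kpol`, `D_Kd`, `efficiency_correct`,
#'   `efficiency_incorrect`, `fidelity`.
#' @examples
#' fidelity_metrics(c(k_pol = 12.0, K_d = 1.5), c(k_pol = 0.134, K_d = 365))
#' @export
fidelity_metrics <- function(correct, incorrect,
                             rounding = c("as_printed", "none")) {
  rounding <- match.arg(rounding)
  correct <- as.list(correct); incorrect <- as.list(incorrect)
  vals <- c(correct$k_pol, correct$K_d, incorrect$k_pol, incorrect$K_d)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("k_pol and K_d must be finite and > 0 for both nucleotides.")
  }
  eff_c <- correct$k_pol / correct$K_d
  eff_i <- incorrect$k_pol / incorrect$K_d
  if (rounding == "as_printed") {
    eff_c_f <- round_sig(eff_c); eff_i_f <- round_sig(eff_i)
  } else {
    eff_c_f <- eff_c; eff_i_f <- eff_i
  }
  tibble(
    D_kpol = correct$k_pol / incorrect$k_pol,
    D_Kd = incorrect$K_d / correct$K_d,
    efficiency_correct = eff_c,
    efficiency_incorrect = eff_i,
    fidelity = (eff_c_f + eff_i_f) / eff_i_f
  )
}

#' Fidelity ratio between two enzymes
#'
#' Fold difference in fidelity, reference enzyme over variant (e.g. wild
#' type over a mutator variant).
#'
#' @param fidelity_wt,fidelity_variant Fidelity values, > 0.
#' @return Dimensionless quotient.
#' @export
x_fold <- function(fidelity_wt, fidelity_variant) {
  if (any(c(fidelity_wt, fidelity_variant) <= 0) ||
      any(!is.finite(c(fidelity_wt, fidelity_variant)))) {
    abort("Fidelities must be finite and > 0.")
  }
  fidelity_wt / fidelity_variant
}

#' Build a fidelity table across base pairs and enzymes
#'
#' Takes a tidy table of single-turnover parameters (one row per
#' enzyme/template/dNTP combination) and derives all discrimination,
#' efficiency, fidelity and fold-difference columns.
#'
#' @param params Data frame with columns `enzyme`, `template`, `dNTP`,
#'   `correct` (logical), `k_pol` (s^-1), `K_d` (uM).
#' @param rounding Passed to [fidelity_metrics()].
#' @param reference_enzyme Enzyme name used as the numerator in the
#'   fold-difference column (default `"WT"`).
#' @return Tibble with one row per enzyme/template: `efficiency_correct`,
#'   `efficiency_incorrect`, `D_kpol`, `D_Kd`, `fidelity`, `x_fold` (NA
#'   for the reference enzyme).
#' @export
fidelity_table <- function(params, rounding = c("as_printed", "none"),
                           reference_enzyme = "WT") {
  rounding <- match.arg(rounding)
  need <- c("enzyme", "template", "dNTP", "correct", "k_pol", "K_d")
  if (!all(need %in% names(params))) {
    abort(paste0("`params` needs columns: ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(params) |>
    dplyr::group_by(.data$enzyme, .data$template) |>
    dplyr::group_modify(function(d, key) {
      if (sum(d$correct) != 1L || sum(!d$correct) != 1L) {
        abort("Each enzyme/template group needs one correct and one incorrect row.")
      }
      cc <- d[d$correct, ]; ii <- d[!d$correct, ]
      res <- fidelity_metrics(c(k_pol = cc$k_pol, K_d = cc$K_d),
                              c(k_pol = ii$k_pol, K_d = ii$K_d), rounding)
      dplyr::bind_cols(
        tibble(dNTP_correct = cc$dNTP, dNTP_incorrect = ii$dNTP), res)
    }) |>
    dplyr::ungroup()
  ref <- out |>
    dplyr::filter(.data$enzyme == reference_enzyme) |>
    dplyr::select("template", ref_fidelity = "fidelity")
  out |>
    dplyr::left_join(ref, by = "template") |>
    dplyr::mutate(
      x_fold = dplyr::if_else(.data$enzyme == reference_enzyme, NA_real_,
                              .data$ref_fidelity / .data$fidelity)
    ) |>
    dplyr::select(-"ref_fidelity")
}

check_progress_curve <- function(times, product, min_points) {
  if (length(times) < min_points) {
    abort(paste0("Need at least ", min_points, " time points."))
  }
  if (length(times) != length(product)) {
    abort("`times` and `product` must have equal length.")
  }
  if (any(diff(times) <= 0) || any(times < 0)) {
    abort("`times` must be strictly increasing and non-negative.")
  }
  check_finite(product, "product")
  invisible(TRUE)
}
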