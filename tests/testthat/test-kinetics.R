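# Burst / single-turnover fitting and fidelity arithmetic.

test_that("burst model has the right limits and steady-state slope", {
  expect_equal(burst_model(0, 100, 9, 1.2), 0)
  # with no steady-state phase the amplitude limit is E_app
  expect_equal(burst_model(1e3, 100, 9, 0), 100)
  # slope of the linear phase at large t
  slope <- (burst_model(100.1, 100, 9, 1.2) - burst_model(100, 100, 9, 1.2)) / 0.1
  expect_equal(slope, 100 * 9 * 1.2 / 10.2, tolerance = 1e-8)
  # k_ss = 0 reduces the standard form to a single exponential
  tt <- seq(0, 1, by = 0.05)
  expect_equal(burst_model(tt, 50, 5, 0), 50 * (1 - exp(-5 * tt)))
  # printed variant follows its formula literally
  expect_equal(
    burst_model(1, 100, 9, 1.2, form = "as_printed"),
    100 * (9 / 10.2^2 * (1 - exp(-10.2)) + 9 * 1.2 / 10.2))
  expect_error(burst_model(1, 100, -1, 1), "non-negative")
})

test_that("burst fit recovers generating parameters on clean data", {
  tt <- exp(seq(log(0.02), log(3), length.out = 25))
  y <- burst_model(tt, 100, 9, 1.2)
  fit <- fit_burst(tt, y)
  expect_equal(fit$E_app, 100, tolerance = 1e-3)
  expect_equal(fit$k_obs, 9, tolerance = 1e-3)
  expect_equal(fit$k_ss, 1.2, tolerance = 1e-3)
  expect_false(fit$degenerate)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("a purely linear progress curve is flagged as burst-degenerate", {
  tt <- seq(0.1, 3, length.out = 20)
  fit <- fit_burst(tt, 5 * tt)
  expect_true(fit$degenerate || !fit$converged)
})

test_that("single-exponential fit is exact on clean data", {
  tt <- seq(0.02, 2, length.out = 20)
  y <- 100 * (1 - exp(-3.6 * tt))
  fit <- fit_single_exponential(tt, y)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$k_obs, 3.6, tolerance = 1e-6)
  # plateau at t >> 1/k equals the amplitude
  expect_equal(100 * (1 - exp(-3.6 * 100)), 100)
  expect_error(fit_single_exponential(tt, rep(0, 20)), "zero")
})

test_that("saturation fit recovers k_pol and K_d and warns off-range", {
  conc <- c(0.5, 1, 2.5, 5, 15, 50, 150, 500, 1500)
  k <- 12 * conc / (1.5 + conc)
  fit <- fit_saturation(conc, k)
  expect_equal(fit$k_pol, 12, tolerance = 1e-6)
  expect_equal(fit$K_d_dNTP, 1.5, tolerance = 1e-6)
  # half-saturation: the model passes through k_pol/2 at [dNTP] = K_d
  expect_equal(12 * 1.5 / (1.5 + 1.5), 12 / 2)
  expect_warning(
    fit_saturation(c(1000, 2000, 4000), 12 * c(1000, 2000, 4000) /
                     (1.5 + c(1000, 2000, 4000))),
    "ill-conditioned")
})

test_that("noisy parameter recovery stays within tolerance (small ensemble)", {
  errs <- purrr::map_dfr(1:10, function(s) {
    scen <- landscape_scenario(curve_noise = 0.03, seed = 100 + s)
    curves <- gen_progress_curves(scen)
    kobs <- curves$single_turnover |>
      dplyr::group_by(dNTP) |>
      dplyr::summarise(
        k_obs = fit_single_exponential(time, product)$k_obs, .groups = "drop")
    fit <- fit_saturation(kobs$dNTP, kobs$k_obs)
    tibble::tibble(e_kpol = abs(fit$k_pol / 12 - 1),
                   e_kd = abs(fit$K_d_dNTP / 1.5 - 1))
  })
  expect_lt(median(errs$e_kpol), 0.10)
  expect_lt(median(errs$e_kd), 0.20)
})

test_that("fidelity metrics reproduce the printed derived values", {
  wt_g <- fidelity_metrics(c(k_pol = 12.0, K_d = 1.5),
                           c(k_pol = 0.134, K_d = 365))
  expect_equal(wt_g$efficiency_correct, 8)
  expect_equal(signif(wt_g$efficiency_incorrect, 2), 3.7e-4)
  expect_equal(wt_g$fidelity, 21623, tolerance = 1e-4)
  expect_equal(wt_g$D_kpol, 90, tolerance = 0.01)
  expect_equal(wt_g$D_Kd, 243, tolerance = 0.01)

  i260q_g <- fidelity_metrics(c(k_pol = 3.6, K_d = 0.6),
                              c(k_pol = 0.095, K_d = 16), rounding = "none")
  expect_equal(i260q_g$fidelity, 1011, tolerance = 1e-3)
  expect_equal(x_fold(21623, 1011), 21.39, tolerance = 1e-3)
  expect_equal(x_fold(6364, 372), 17.11, tolerance = 1e-3)
  expect_equal(x_fold(5, 5), 1)
  expect_error(fidelity_metrics(c(k_pol = -1, K_d = 1), c(k_pol = 1, K_d = 1)),
               "> 0")
  expect_error(x_fold(0, 1), "> 0")
})

test_that("fidelity exceeds 1 and approaches 1 + eff_c/eff_i", {
  expect_equal(
    fidelity_metrics(c(k_pol = 1, K_d = 1), c(k_pol = 1, K_d = 1))$fidelity, 2)
  set.seed(13)
  for (i in 1:20) {
    cc <- c(k_pol = runif(1, 1, 20), K_d = runif(1, 0.5, 5))
    ii <- c(k_pol = runif(1, 0.01, 0.5), K_d = runif(1, 10, 500))
    f <- fidelity_metrics(cc, ii, rounding = "none")
    expect_gt(f$fidelity, 1)
    expect_equal(f$fidelity,
                 1 + f$efficiency_correct / f$efficiency_incorrect)
  }
})

test_that("the fidelity table derives every column per enzyme/template", {
  params <- tibble::tribble(
    ~enzyme, ~template, ~dNTP, ~correct, ~k_pol, ~K_d,
    "WT",    "G", "dC", TRUE,  12.0,  1.5,
    "WT",    "G", "dA", FALSE, 0.134, 365,
    "I260Q", "G", "dC", TRUE,  3.6,   0.6,
    "I260Q", "G", "dA", FALSE, 0.095, 16
  )
  tbl <- fidelity_table(params)
  expect_equal(nrow(tbl), 2L)
  wt <- tbl[tbl$enzyme == "WT", ]
  mut <- tbl[tbl$enzyme == "I260Q", ]
  expect_true(is.na(wt$x_fold))
  expect_equal(mut$x_fold, wt$fidelity / mut$fidelity)
  expect_equal(wt$efficiency_correct, 8)
  expect_error(fidelity_table(params[1:3, ]), "one correct and one incorrect")
})
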