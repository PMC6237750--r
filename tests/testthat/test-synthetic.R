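# Seeded generators: reproducibility and round-trip with the fit stages.

test_that("identical seeds give byte-identical generator output", {
  s1 <- landscape_scenario(seed = 99)
  s2 <- landscape_scenario(seed = 99)
  expect_identical(gen_peak_lists(s1), gen_peak_lists(s2))
  expect_identical(gen_progress_curves(s1), gen_progress_curves(s2))
  expect_identical(gen_cpmg(s1), gen_cpmg(s2))
  expect_identical(gen_stopped_flow(s1, "trap"), gen_stopped_flow(s2, "trap"))
  # different seeds differ
  expect_false(identical(gen_peak_lists(s1),
                         gen_peak_lists(landscape_scenario(seed = 100))))
})

test_that("full closure without noise reproduces the closed reference", {
  sc <- gen_peak_lists(quiet_scenario(closure_fraction = 1,
                                      n_off_pathway = 0, seed = 2))
  expect_equal(sc$test$dH_ppm, sc$closed$dH_ppm)
  expect_equal(sc$test$dC_ppm, sc$closed$dC_ppm)
})

test_that("scenario validation rejects impossible settings", {
  expect_error(landscape_scenario(closure_fraction = 1.5), "\\[0, 1\\]")
  expect_error(landscape_scenario(sigma_H = -1), ">= 0")
})

test_that("noise-free progress curves are exactly invertible by the fits", {
  curves <- gen_progress_curves(quiet_scenario(seed = 23), noise_free = TRUE)
  bf <- fit_burst(curves$burst$time, curves$burst$product)
  expect_equal(bf$k_obs, 9, tolerance = 1e-3)
  expect_equal(bf$k_ss, 1.2, tolerance = 1e-3)
  kobs <- curves$single_turnover |>
    dplyr::group_by(dNTP) |>
    dplyr::summarise(k_obs = fit_single_exponential(time, product)$k_obs,
                     .groups = "drop")
  expect_equal(kobs$k_obs, curves$kobs_table$k_obs, tolerance = 1e-6)
  sat <- fit_saturation(kobs$dNTP, kobs$k_obs)
  expect_equal(sat$k_pol, 12, tolerance = 1e-5)
  expect_equal(sat$K_d_dNTP, 1.5, tolerance = 1e-5)
})

test_that("noise-free CPMG curves give exact parameter recovery", {
  d <- gen_cpmg(landscape_scenario(n_flat = 2, n_dispersive = 2, seed = 41),
                noise_free = TRUE)
  fits <- fit_dispersion_panel(d$data)
  disp <- dplyr::inner_join(fits, d$truth[d$truth$dispersive, ],
                            by = "residue")
  expect_equal(disp$R_ex.x, disp$R_ex.y, tolerance = 1e-4)
  expect_equal(disp$k_ex.x, disp$k_ex.y, tolerance = 1e-4)
  expect_true(all(disp$flexible))
})

test_that("stopped-flow traces start after the dead time with a fast phase", {
  scen <- quiet_scenario(sf_dNTP = c(25), seed = 19)
  tr <- gen_stopped_flow(scen, "forward", noise_free = TRUE)[[1]]
  expect_gte(min(tr$time), scen$dead_time)
  # biphasic observable: a fast phase on the ~1/(k3+km3) timescale followed
  # by slower relaxation leaves an interior extremum in the trace
  peak <- which.max(tr$signal)
  expect_gt(peak, 1L)
  expect_lt(peak, nrow(tr))
  expect_lt(tr$time[peak], 5 / (124 + 11.5) + 0.3)
})

test_that("spectra generators place the donor band and handle disjoint bands", {
  sp <- gen_spectra()
  expect_equal(sp$donor$wavelength_nm[which.max(sp$donor$value)], 490)
  disj <- gen_spectra(mode = "rectangular", rect_donor = c(420, 430),
                      rect_acceptor = c(500, 510))
  expect_equal(disj$J_analytic, 0)
})
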