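# FRET efficiency, overlap integral, Forster radius and distances.

test_that("transfer efficiency covers the quenching extremes", {
  expect_equal(efret(10, 10), 0)
  expect_equal(efret(0, 10), 1)
  expect_equal(efret(5, 10), 0.5)
  expect_warning(e <- efret(12, 10), "outside")
  expect_equal(e, -0.2)
  expect_error(efret(1, 0), "> 0")
})

test_that("spectrum construction validates its grid", {
  expect_s3_class(spectrum(400:410, rep(1, 11)), "spectrum")
  expect_error(spectrum(c(400, 400), c(1, 1)), "increasing")
  expect_error(spectrum(401:410, rep(-1, 10), "emission"), ">= 0")
})

test_that("overlap integral matches the rectangular closed form", {
  sp <- gen_spectra(mode = "rectangular")
  J <- overlap_integral(sp$donor, sp$acceptor)
  expect_equal(J, sp$J_analytic, tolerance = 1e-3)
  # linearity: doubling the extinction doubles J
  acc2 <- spectrum(sp$acceptor$wavelength_nm, 2 * sp$acceptor$value,
                   "extinction")
  expect_equal(overlap_integral(sp$donor, acc2), 2 * J, tolerance = 1e-10)
  # zero extinction gives zero overlap
  acc0 <- spectrum(sp$acceptor$wavelength_nm, rep(0, nrow(sp$acceptor)),
                   "extinction")
  expect_equal(overlap_integral(sp$donor, acc0), 0)
  # disjoint supports are an error
  d <- spectrum(400:450, rep(1, 51), "emission")
  a <- spectrum(500:550, rep(1e4, 51), "extinction")
  expect_error(overlap_integral(d, a), "disjoint")
})

test_that("overlap integral converges under grid refinement", {
  err <- vapply(c(2, 0.5, 0.1), function(by) {
    sp <- gen_spectra(mode = "rectangular", grid = seq(400, 600, by = by))
    abs(overlap_integral(sp$donor, sp$acceptor) / sp$J_analytic - 1)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12 + 0))
  expect_lt(err[3], 1e-3)
})

test_that("Forster radius reproduces the working value and its scaling", {
  expect_equal(forster_radius(2.36e-14), 37.8, tolerance = 3e-3)
  # invert the radius relation for J, then round-trip
  J0 <- (37.76 / 9.78e3)^6 / ((2 / 3) * 1.344^-4 * 0.7)
  expect_equal(forster_radius(J0), 37.76, tolerance = 1e-10)
  expect_equal(forster_radius(J0 * 2^6), 2 * forster_radius(J0))
  expect_error(forster_radius(2.36e-14, kappa2 = 0), "> 0")
})

test_that("distance and efficiency are exact inverses", {
  expect_equal(distance_from_efficiency(0.5, 37.76), 37.76)
  # r = R0 * 2^(1/6) corresponds to E = 1/3
  expect_equal(efficiency_from_distance(37.76 * 2^(1 / 6), 37.76), 1 / 3)
  E <- seq(0.01, 0.99, by = 0.01)
  r <- distance_from_efficiency(E, 37.76)
  expect_equal(efficiency_from_distance(r, 37.76), E, tolerance = 1e-12)
  # larger efficiency means shorter distance
  expect_true(all(diff(r) < 0))
  expect_error(distance_from_efficiency(1, 37.76), "strictly inside")
  expect_error(distance_from_efficiency(0, 37.76), "strictly inside")
})
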