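# Chemical-shift vector metrics and state classification.

test_that("combined shift and vector magnitude match hand arithmetic", {
  expect_equal(combined_shift(0, 0), 0)
  expect_equal(combined_shift(0.05, 0.2), sqrt((0.0025 + 0.01) / 2))
  expect_equal(combined_shift(0.05, 0.2), 0.07906, tolerance = 1e-3)
  # a pure-proton 0.025 ppm shift falls below the 0.025 combined threshold
  expect_equal(combined_shift(0.025, 0), 0.01768, tolerance = 1e-3)
  expect_equal(shift_vector_magnitude(0, 0), 0)
  expect_equal(shift_vector_magnitude(0.1, 0), 0.1)
  expect_equal(shift_vector_magnitude(0, 1.0), 0.2514)
  expect_error(combined_shift(NA_real_, 0), "finite")
  expect_error(shift_vector_magnitude(Inf, 0), "finite")
})

test_that("shift metrics are absolutely homogeneous in the inputs", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(1); y <- rnorm(1); a <- rnorm(1)
    expect_equal(combined_shift(a * x, a * y), abs(a) * combined_shift(x, y))
    expect_equal(shift_vector_magnitude(a * x, a * y),
                 abs(a) * shift_vector_magnitude(x, y))
  }
})

test_that("normalized magnitude scales and flags degenerate references", {
  expect_equal(normalized_magnitude(0.1, 0.4, 0.1, 0.4), 1)
  expect_equal(normalized_magnitude(0.05, 0.2, 0.1, 0.4), 0.5)
  expect_true(is.na(normalized_magnitude(0.1, 0.1, 1e-8, 0)))
})

test_that("cos theta captures collinearity, orthogonality and sign", {
  expect_equal(cos_theta(0.2, 0.8, 0.1, 0.4), 1)
  # orthogonal in the scaled plane: (0.1, 0) vs (0, 0.4)
  expect_equal(cos_theta(0.1, 0, 0, 0.4), 0)
  expect_equal(cos_theta(-0.1, -0.4, 0.1, 0.4), -1)
  expect_true(is.na(cos_theta(0, 0, 0.1, 0.4)))
  set.seed(7)
  for (i in 1:25) {
    v <- rnorm(2); w <- rnorm(2); a <- runif(1, 0.1, 10)
    base <- cos_theta(v[1], v[2], w[1], w[2])
    expect_equal(cos_theta(a * v[1], a * v[2], w[1], w[2]), base)
    expect_equal(cos_theta(-v[1], -v[2], w[1], w[2]), -base)
    expect_gte(base, -1); expect_lte(base, 1)
  }
})

test_that("rmsd_one matches hand values and a brute-force loop", {
  expect_equal(rmsd_one(c(1, 1), c(1, 1)), 0)
  expect_equal(rmsd_one(0.8, 0.5), sqrt(0.04 + 0.25))
  expect_equal(rmsd_one(0.8, 0.5), 0.53852, tolerance = 1e-4)
  expect_equal(rmsd_one(c(1, 0.8), c(1, 0.5)), sqrt(0.29 / 2))
  expect_equal(rmsd_one(c(1, 0.8), c(1, 0.5)), 0.38079, tolerance = 1e-4)
  expect_error(rmsd_one(numeric(0), numeric(0)), "non-empty")
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    ct <- runif(n, -1, 1); dn <- runif(n, 0, 2)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (1 - ct[j])^2 + (1 - dn[j])^2
    expect_equal(rmsd_one(ct, dn), sqrt(acc / n))
  }
})

test_that("significance threshold averages replicate variability", {
  base <- tibble::tibble(residue = 1:5, restype = "I", methyl = "CD1",
                         dH_ppm = seq(0.1, 0.5, by = 0.1), dC_ppm = 10:14)
  expect_equal(significance_threshold(list(base, base)), 0)
  shifted <- dplyr::mutate(base, dH_ppm = dH_ppm + 0.02)
  expect_equal(significance_threshold(list(base, shifted)),
               1.5 * combined_shift(0.02, 0))
  expect_equal(significance_threshold(list(base, shifted)), 0.02121,
               tolerance = 1e-3)
  # between-group mode pairs across the two groups
  expect_equal(
    significance_threshold(list(base, shifted), groups = c("WT", "MUT"),
                           mode = "between"),
    1.5 * combined_shift(0.02, 0))
  expect_error(significance_threshold(list(base), groups = "WT"), "at least two")
})

test_that("classification follows the strict threshold and cosine rules", {
  expect_equal(classify_residue(0.03, 0.9), "on_pathway")
  expect_equal(classify_residue(0.02, 0.9), "not_significant")
  expect_equal(classify_residue(0.025, 0.9), "not_significant") # strict
  expect_equal(classify_residue(0.03, 0.5), "off_pathway")
  expect_equal(classify_residue(0.03, 0.8), "on_pathway") # only < 0.8 is off
  expect_equal(classify_residue(0.03, NA), "reference_degenerate")
  expect_error(classify_residue(0.03, 0.9, threshold = -1), ">= 0")
})

test_that("comparing a state to itself and to the closed reference works", {
  sc <- gen_peak_lists(quiet_scenario(n_off_pathway = 0, seed = 21))
  closed_cmp <- compare_states(sc$closed, sc$open, sc$closed)
  sig <- closed_cmp$rows$classification == "on_pathway"
  expect_true(all(sig))
  expect_equal(closed_cmp$rows$delta_n, rep(1, nrow(closed_cmp$rows)))
  expect_equal(closed_cmp$rows$cos_theta, rep(1, nrow(closed_cmp$rows)))
  expect_equal(closed_cmp$rmsd_global, 0)

  open_cmp <- compare_states(sc$open, sc$open, sc$closed)
  expect_true(all(open_cmp$rows$classification == "not_significant"))
})

test_that("classification counts are conserved over matched peaks", {
  sc <- gen_peak_lists(landscape_scenario(seed = 5))
  cmp <- compare_states(sc$test, sc$open, sc$closed)
  expect_equal(sum(cmp$counts$n), nrow(cmp$rows))
  expect_equal(cmp$summary$n_on_pathway + cmp$summary$n_off_pathway +
                 cmp$summary$n_not_significant +
                 cmp$summary$n_reference_degenerate,
               cmp$summary$n_matched)
})

test_that("disjoint peak lists and bad subdomain maps are errors", {
  a <- peak_list(tibble::tibble(residue = 1:3, restype = "I", methyl = "CD1",
                                dH_ppm = 0.5, dC_ppm = 12))
  b <- peak_list(tibble::tibble(residue = 4:6, restype = "I", methyl = "CD1",
                                dH_ppm = 0.5, dC_ppm = 12))
  expect_error(compare_states(a, b, b), "common")
  bad_map <- tibble::tibble(subdomain = "lyase", start = 1, end = 2)
  expect_error(compare_states(a, a, a, subdomains = bad_map), "subdomain")
})

test_that("re-referencing to an anchor removes a global offset", {
  sc <- gen_peak_lists(quiet_scenario(seed = 3))
  shifted <- sc$test
  shifted$dH_ppm <- shifted$dH_ppm + 0.05
  shifted$dC_ppm <- shifted$dC_ppm + 0.3
  anchor <- shifted[1, ]
  fixed <- rereference_peaks(shifted, sc$test, residue = anchor$residue,
                             methyl = anchor$methyl)
  expect_equal(fixed$dH_ppm, sc$test$dH_ppm)
  expect_equal(fixed$dC_ppm, sc$test$dC_ppm)
})

test_that("tidy/glance/autoplot methods work on comparisons", {
  sc <- gen_peak_lists(landscape_scenario(seed = 9))
  cmp <- compare_states(sc$test, sc$open, sc$closed)
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(glance(cmp)), 1L)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(plot_subdomain_rmsd(cmp), "ggplot")
})
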