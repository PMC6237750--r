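# Mass-action scheme, stiff simulation, trap fits and global fitting.

test_that("scheme construction enforces species and moiety conservation", {
  expect_s3_class(polb_scheme("WT"), "kinetic_scheme")
  expect_error(
    kinetic_scheme("A", tibble::tibble(reactants = list("A"),
                                       products = list("B"), rate = "k"),
                   c(k = 1), tibble::tibble(species = "A", M = 1)),
    "unknown species")
  # a reaction that destroys a moiety is rejected
  expect_error(
    kinetic_scheme(c("A", "B"),
                   tibble::tibble(reactants = list("A"), products = list("B"),
                                  rate = "k"),
                   c(k = 1),
                   tibble::tibble(species = c("A", "B"), M = c(1, 0))),
    "conserve")
})

test_that("simulation conserves enzyme and DNA and matches two-state theory", {
  sch <- polb_scheme("WT")
  tt <- seq(0, 2, by = 0.002)
  sim <- simulate_scheme(sch, c(E = 0.25, D = 0.1, N = 10), tt)
  expect_lt(attr(sim, "conservation_error"), 1e-6)

  # isolated closing step: relaxation at k3 + km3 = 135.5 s^-1 toward an
  # equilibrium closed fraction of 124/135.5
  two <- two_state_scheme(124, 11.5)
  tt2 <- seq(0, 0.1, by = 5e-4)
  sim2 <- simulate_scheme(two, c(EDN = 1), tt2)
  analytic <- 124 / 135.5 * (1 - exp(-135.5 * tt2))
  expect_lt(max(abs(sim2$cDN[-1] - analytic[-1]) / analytic[-1]), 1e-5)
})

test_that("without dNTP no ternary species are ever populated", {
  sim <- simulate_scheme(polb_scheme("WT"), c(E = 0.25, D = 0.1),
                         seq(0, 1, by = 0.01))
  expect_equal(max(abs(c(sim$EDN, sim$cDN, sim$nDN, sim$EP))), 0)
})

test_that("equal amplitudes over enzyme species give a constant signal", {
  sch <- polb_scheme("WT")
  amps <- setNames(rep(2, 6), c("E", "ED", "EDN", "cDN", "nDN", "EP"))
  sim <- simulate_scheme(sch, c(E = 0.25, D = 0.1, N = 5),
                         seq(0, 0.5, by = 0.005), amplitudes = amps,
                         baseline = 0)
  expect_equal(sim$signal, rep(2 * 0.25, nrow(sim)), tolerance = 1e-7)
})

test_that("the isolated binding step satisfies detailed balance", {
  species <- c("ED", "N", "EDN")
  sch <- kinetic_scheme(
    species,
    tibble::tibble(reactants = list(c("ED", "N"), "EDN"),
                   products = list("EDN", c("ED", "N")),
                   rate = c("k2", "km2")),
    c(k2 = 100, km2 = 150),
    tibble::tibble(species = species, E = c(1, 0, 1), N = c(0, 1, 1)))
  sim <- simulate_scheme(sch, c(ED = 0.3, N = 5), seq(0, 1, by = 0.01))
  fin <- sim[nrow(sim), ]
  expect_equal(fin$EDN / (fin$ED * fin$N), 100 / 150, tolerance = 1e-4)
})

test_that("dead-time masking counts points and handles artifacts", {
  tr <- tibble::tibble(time = seq(0, 0.01, by = 0.001), signal = 1:11)
  expect_equal(nrow(dead_time_mask(tr, 0)), 11L)
  # 2 ms dead time on a 1 ms grid removes the first two points
  expect_equal(nrow(dead_time_mask(tr, 0.002)), 9L)
  expect_error(dead_time_mask(tr, 1), "no points")
  art <- tibble::tibble(time = tr$time, signal = rep(1, 11))
  expect_equal(dead_time_mask(tr, 0, art)$signal, (1:11) - 1)
})

test_that("trap relaxation recovers its three generating rates", {
  tr <- gen_stopped_flow(landscape_scenario(seed = 3), "trap",
                         noise_free = TRUE)
  fit <- fit_triple_exponential(tr)
  expect_equal(fit$rates, c(163, 48.2, 5), tolerance = 0.05)
  expect_equal(fit$n_exp_best, 3)
  expect_equal(fit$assignment$step[1], "k_minus4 (reverse non-covalent)")
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("model comparison prefers two exponentials for biexponential decay", {
  tt <- seq(0, 1, by = 0.002)
  y <- 0.3 + 0.5 * exp(-40 * tt) + 0.4 * exp(-4 * tt)
  set.seed(1)
  y <- y + rnorm(length(y), 0, 0.002)
  fit <- fit_triple_exponential(tibble::tibble(time = tt, signal = y))
  expect_equal(fit$n_exp_best, 2)
  expect_error(
    fit_triple_exponential(tibble::tibble(time = tt, signal = rep(1, length(tt)))),
    "constant")
})

test_that("constrained global fit recovers the free rates from clean traces", {
  scen <- quiet_scenario(sf_dNTP = c(2.5, 10, 50), seed = 11)
  traces <- lapply(gen_stopped_flow(scen, "forward", noise_free = TRUE),
                   thin_trace, by = 5)
  start <- polb_scheme("WT", rates = c(k3 = 60, k4 = 50))
  fit <- fit_global(traces, start, free = c("k3", "k4"), n_starts = 2,
                    seed = 2)
  expect_equal(unname(fit$free["k3"]), 124, tolerance = 0.01)
  expect_equal(unname(fit$free["k4"]), 20, tolerance = 0.01)
  expect_false(fit$ill_conditioned)
  expect_error(fit_global(traces, start, free = "k5"), "constrained")
})

test_that("with all rates fixed the fit reduces to a linear amplitude solve", {
  scen <- quiet_scenario(sf_dNTP = c(10), seed = 4)
  traces <- lapply(gen_stopped_flow(scen, "forward", noise_free = TRUE),
                   thin_trace, by = 10)
  fit <- fit_global(traces, scen$scheme, free = character(0))
  expect_lt(fit$residual_norm, 1e-6)
  amp <- fit$amplitudes[[1]]
  expect_equal(unname(amp["cDN"]), 1.6, tolerance = 1e-4)
  expect_equal(unname(amp["baseline"]), 0.3, tolerance = 1e-4)
})
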