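# Seeded generators for every input the pipeline consumes: methyl peak
# lists with a known closure fraction, progress curves and stopped-flow
# traces from the kinetic models, CPMG panels, and donor/acceptor spectra.
# Ground truth is retained so every analysis stage can be scored against
# the values that generated its input.

#' Describe a synthetic conformational-landscape scenario
#'
#' Bundles all generator settings with a seed. Defaults emulate the study
#' conditions: a partially closed test state (closure fraction 0.5, the
#' regime seen for the mutator binary complex) with a few off-pathway
#' resonances; wild-type burst (9 s^-1 fast phase, 1.2 s^-1 steady state)
#' and single-turnover (k_pol 12 s^-1, K_d 1.5 uM, dNTP titrated
#' 0.5-1500 uM) kinetics; the wild-type incorporation scheme for
#' stopped-flow traces with a 2 ms dead time; a 40-residue CPMG panel
#' with 14 dispersive members (the count seen for the correct ternary
#' complex); and IAEDANS-like donor emission peaking at 490 nm against a
#' dabcyl-like acceptor band.
#'
#' @param n_peaks Number of methyl peaks in the reference lists.
#' @param closure_fraction Fractional closure f of the test state in
#'   \[0, 1\].
#' @param n_off_pathway Number of peaks given a purely orthogonal
#'   (off-pathway) perturbation instead of the closure interpolation.
#' @param off_magnitude Magnitude of that orthogonal offset in the scaled
#'   shift plane (ppm).
#' @param sigma_H,sigma_C Gaussian peak-position noise (ppm).
#' @param ref_magnitude_range Range of reference (open to closed) vector
#'   magnitudes in the scaled plane (ppm).
#' @param burst Named vector `E_app` (nM), `k_obs`, `k_ss` (s^-1).
#' @param saturation Named vector `k_pol` (s^-1), `K_d` (uM).
#' @param dNTP_series dNTP concentrations (uM) for single-turnover curves.
#' @param curve_noise Relative Gaussian noise on progress curves.
#' @param scheme [polb_scheme()] used for stopped-flow simulation.
#' @param sf_dNTP dNTP concentrations (uM) for the stopped-flow series.
#' @param E0,D0 Post-mixing enzyme and DNA concentrations (uM).
#' @param amplitudes,baseline Fluorescence model for the simulated signal.
#' @param sf_noise Absolute Gaussian noise on the fluorescence signal (V).
#' @param dead_time Instrument dead time (s).
#' @param trap_rates Rates (s^-1) of the three sequential trap-relaxation
#'   steps: reverse non-covalent, reverse fingers closing, dNTP release.
#' @param n_flat,n_dispersive CPMG panel composition.
#' @param cpmg_noise Gaussian noise on R2_eff (s^-1).
#' @param nu_cpmg CPMG refocusing-frequency grid (s^-1).
#' @param R2_0_range,R_ex_range,k_ex_range Parameter ranges for the
#'   dispersive panel members.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return List of class `landscape_scenario`.
#' @export
landscape_scenario <- function(
    n_peaks = 60, closure_fraction = 0.5, n_off_pathway = 4,
    off_magnitude = 0.08, sigma_H = 0.002, sigma_C = 0.008,
    ref_magnitude_range = c(0.03, 0.2),
    burst = c(E_app = 100, k_obs = 9, k_ss = 1.2),
    saturation = c(k_pol = 12, K_d = 1.5),
    dNTP_series = c(0.5, 1, 2.5, 5, 15, 50, 150, 500, 1500),
    curve_noise = 0.03,
    scheme = polb_scheme("WT"),
    sf_dNTP = c(1, 2.5, 5, 10, 25, 50),
    E0 = 0.25, D0 = 0.1,
    amplitudes = c(ED = 3.0, EDN = 2.8, cDN = 1.6, nDN = 1.2, EP = 2.4),
    baseline = 0.3, sf_noise = 0.01, dead_time = 0.002,
    trap_rates = c(163, 48.2, 5),
    n_flat = 26, n_dispersive = 14, cpmg_noise = 0.2,
    nu_cpmg = c(25, 50, 75, 100, 150, 200, 300, 400, 600, 800, 1000, 1400,
                2000),
    R2_0_range = c(10, 20), R_ex_range = c(3, 8), k_ex_range = c(800, 2500),
    seed = 1L) {
  if (closure_fraction < 0 || closure_fraction > 1) {
    abort("`closure_fraction` must lie in [0, 1].")
  }
  if (any(c(sigma_H, sigma_C, curve_noise, sf_noise, cpmg_noise) < 0)) {
    abort("Noise levels must be >= 0.")
  }
  structure(as.list(environment()), class = "landscape_scenario")
}

#' Generate open, closed and test methyl peak lists
#'
#' The open reference is drawn in realistic ILV methyl ranges (1H 0-1.5
#' ppm, 13C 9-27 ppm, residues 1-335); the closed reference displaces each
#' peak along a random direction in the scaled shift plane. Test peaks are
#' the fractional-closure interpolation `open + f (closed - open)` plus
#' Gaussian noise; peaks in the off-pathway set instead receive a purely
#' orthogonal offset (rotated 90 degrees in the scaled plane), so their
#' intended classification is known analytically.
#'
#' @param scenario A [landscape_scenario()].
#' @return List with `open`, `closed`, `test` peak lists and a `truth`
#'   tibble (per-peak fraction, off-pathway flag).
#' @export
gen_peak_lists <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_peaks
  restype <- sample(c("I", "L", "V"), n, replace = TRUE)
  residue <- sort(sample(seq_len(335), n, replace = TRUE))
  # non-stereospecific Leu/Val methyls may appear twice; distinct methyl ids
  methyl <- vapply(seq_len(n), function(i) {
    base <- switch(restype[i], I = "CD1", L = sample(c("CD1", "CD2"), 1),
                   V = sample(c("CG1", "CG2"), 1))
    base
  }, character(1))
  key <- paste(residue, methyl)
  dup <- duplicated(key)
  while (any(dup)) {
    methyl[dup] <- paste0(methyl[dup], "b")
    dup <- duplicated(paste(residue, methyl))
  }
  open <- tibble(
    residue = residue, restype = restype, methyl = methyl,
    dH_ppm = runif(n, 0, 1.5), dC_ppm = runif(n, 9, 27)
  )
  # reference vector in the scaled (H, 0.2514 C) plane
  ang <- runif(n, 0, 2 * pi)
  mag <- runif(n, scenario$ref_magnitude_range[1], scenario$ref_magnitude_range[2])
  ref_sH <- mag * cos(ang)
  ref_sC <- mag * sin(ang)
  closed <- open
  closed$dH_ppm <- open$dH_ppm + ref_sH
  closed$dC_ppm <- open$dC_ppm + ref_sC / CARBON_SCALE

  off <- rep(FALSE, n)
  if (scenario$n_off_pathway > 0) {
    off[sample(n, min(scenario$n_off_pathway, n))] <- TRUE
  }
  f <- scenario$closure_fraction
  test <- open
  # on-pathway: fractional closure along the reference vector
  test$dH_ppm <- open$dH_ppm + f * ref_sH
  test$dC_ppm <- open$dC_ppm + f * ref_sC / CARBON_SCALE
  # off-pathway: orthogonal displacement only (90-degree rotation of the
  # unit reference vector in the scaled plane)
  orth_sH <- -ref_sC / mag * scenario$off_magnitude
  orth_sC <- ref_sH / mag * scenario$off_magnitude
  test$dH_ppm[off] <- open$dH_ppm[off] + orth_sH[off]
  test$dC_ppm[off] <- open$dC_ppm[off] + orth_sC[off] / CARBON_SCALE
  if (scenario$sigma_H > 0) {
    test$dH_ppm <- test$dH_ppm + rnorm(n, 0, scenario$sigma_H)
  }
  if (scenario$sigma_C > 0) {
    test$dC_ppm <- test$dC_ppm + rnorm(n, 0, scenario$sigma_C)
  }
  list(
    open = peak_list(open, "open_reference"),
    closed = peak_list(closed, "closed_reference"),
    test = peak_list(test, "synthetic_test"),
    truth = tibble(residue = residue, methyl = methyl,
                   fraction = ifelse(off, NA_real_, f), off_pathway = off,
                   ref_magnitude = mag)
  )
}

#' Generate burst and single-turnover progress curves
#'
#' Burst curves follow the biphasic model; single-turnover curves are
#' single exponentials whose observed rates follow the hyperbolic
#' saturation law across the dNTP titration. Noise is multiplicative
#' Gaussian at `curve_noise` relative amplitude.
#'
#' @param scenario A [landscape_scenario()].
#' @param noise_free Generate without noise (oracle mode).
#' @return List with `burst` (tibble time/product), `single_turnover`
#'   (tibble dNTP/time/product), `kobs_table` (dNTP, true k_obs) and
#'   `truth` parameters.
#' @export
gen_progress_curves <- function(scenario, noise_free = FALSE) {
  set.seed(scenario$seed)
  b <- scenario$burst
  s <- scenario$saturation
  bt <- exp(seq(log(0.02), log(3), length.out = 25))
  bp <- burst_model(bt, b[["E_app"]], b[["k_obs"]], b[["k_ss"]])
  st <- purrr::map_dfr(scenario$dNTP_series, function(conc) {
    k <- s[["k_pol"]] * conc / (s[["K_d"]] + conc)
    tt <- seq(0.02, max(5 / k, 0.2), length.out = 15)
    tibble(dNTP = conc, time = tt,
           product = 100 * (1 - exp(-k * tt)))
  })
  if (!noise_free && scenario$curve_noise > 0) {
    bp <- bp + rnorm(length(bp), 0, scenario$curve_noise * max(bp))
    st$product <- st$product +
      rnorm(nrow(st), 0, scenario$curve_noise * 100)
  }
  list(
    burst = tibble(time = bt, product = bp),
    single_turnover = st,
    kobs_table = tibble(
      dNTP = scenario$dNTP_series,
      k_obs = s[["k_pol"]] * scenario$dNTP_series /
        (s[["K_d"]] + scenario$dNTP_series)),
    truth = list(burst = b, saturation = s)
  )
}

#' Generate stopped-flow fluorescence traces
#'
#' Forward traces simulate the full incorporation scheme at each dNTP
#' concentration of the series and assemble the FRET observable from the
#' amplitude map; points inside the instrument dead time are discarded.
#' The trap configuration starts from the pre-formed post-non-covalent
#' ternary complex and relaxes through the two reverse conformational
#' steps followed by dNTP release, with rebinding suppressed (the trap
#' sequesters released nucleotide), giving a triple-exponential decay.
#'
#' @param scenario A [landscape_scenario()].
#' @param mode `"forward"` (dNTP series) or `"trap"`.
#' @param noise_free Generate without noise.
#' @return For `"forward"`: list of trace tibbles (attributes `E0`, `D0`,
#'   `dNTP`). For `"trap"`: a single trace tibble with attribute `rates`.
#' @export
gen_stopped_flow <- function(scenario, mode = c("forward", "trap"),
                             noise_free = FALSE) {
  mode <- match.arg(mode)
  set.seed(scenario$seed)
  times <- seq(0, 1, by = 0.001)
  if (mode == "forward") {
    traces <- lapply(scenario$sf_dNTP, function(conc) {
      sim <- simulate_scheme(scenario$scheme,
                             c(E = scenario$E0, D = scenario$D0, N = conc),
                             times, amplitudes = scenario$amplitudes,
                             baseline = scenario$baseline)
      tr <- tibble(time = sim$time, signal = sim$signal)
      if (!noise_free && scenario$sf_noise > 0) {
        tr$signal <- tr$signal + rnorm(nrow(tr), 0, scenario$sf_noise)
      }
      tr <- tr[tr$time >= scenario$dead_time, ]
      attr(tr, "E0") <- scenario$E0
      attr(tr, "D0") <- scenario$D0
      attr(tr, "dNTP") <- conc
      tr
    })
    return(traces)
  }
  k <- scenario$trap_rates
  species <- c("nDN", "cDN", "EDN", "ED", "N")
  trap <- kinetic_scheme(
    species,
    tibble(reactants = list("nDN", "cDN", "EDN"),
           products = list("cDN", "EDN", c("ED", "N")),
           rate = c("km4", "km3", "krel")),
    c(km4 = k[1], km3 = k[2], krel = k[3]),
    tibble(species = species,
           E = c(1, 1, 1, 1, 0), D = c(1, 1, 1, 1, 0), N = c(1, 1, 1, 0, 1))
  )
  tt <- seq(0, 1.5, by = 0.001)
  amps <- c(nDN = 1.2, cDN = 1.6, EDN = 2.8, ED = 3.0)
  sim <- simulate_scheme(trap, c(nDN = scenario$D0), tt,
                         amplitudes = amps, baseline = scenario$baseline)
  tr <- tibble(time = sim$time, signal = sim$signal)
  if (!noise_free && scenario$sf_noise > 0) {
    tr$signal <- tr$signal + rnorm(nrow(tr), 0, scenario$sf_noise)
  }
  tr <- tr[tr$time >= scenario$dead_time, ]
  attr(tr, "rates") <- k
  tr
}

#' Generate a CPMG dispersion panel
#'
#' Flat members have constant R2_eff = R2_0; dispersive members follow the
#' fast-exchange model with parameters drawn from the scenario ranges.
#' Gaussian noise is added at `cpmg_noise` and ground-truth labels are
#' retained.
#'
#' @param scenario A [landscape_scenario()].
#' @param noise_free Generate without noise.
#' @return List with `data` (long tibble residue/nu_cpmg/R2_eff/sigma) and
#'   `truth` (per-residue parameters and the dispersive label).
#' @export
gen_cpmg <- function(scenario, noise_free = FALSE) {
  set.seed(scenario$seed)
  n_tot <- scenario$n_flat + scenario$n_dispersive
  dispersive <- rep(c(FALSE, TRUE), c(scenario$n_flat, scenario$n_dispersive))
  truth <- tibble(
    residue = seq_len(n_tot),
    dispersive = dispersive,
    R2_0 = runif(n_tot, scenario$R2_0_range[1], scenario$R2_0_range[2]),
    R_ex = ifelse(dispersive,
                  runif(n_tot, scenario$R_ex_range[1], scenario$R_ex_range[2]),
                  0),
    k_ex = ifelse(dispersive,
                  runif(n_tot, scenario$k_ex_range[1], scenario$k_ex_range[2]),
                  NA_real_)
  )
  data <- purrr::pmap_dfr(truth, function(residue, dispersive, R2_0, R_ex, k_ex) {
    r2 <- if (dispersive) {
      r2_model(scenario$nu_cpmg, R2_0, R_ex, k_ex)
    } else rep(R2_0, length(scenario$nu_cpmg))
    tibble(residue = residue, nu_cpmg = scenario$nu_cpmg, R2_eff = r2,
           sigma = scenario$cpmg_noise)
  })
  if (!noise_free && scenario$cpmg_noise > 0) {
    data$R2_eff <- data$R2_eff + rnorm(nrow(data), 0, scenario$cpmg_noise)
  }
  list(data = data, truth = truth)
}

#' Generate donor emission and acceptor extinction spectra
#'
#' Gaussian mode emulates IAEDANS emission (peak 490 nm) and a
#' dabcyl-like acceptor absorption band; rectangular mode produces
#' box-shaped spectra whose overlap integral has a polynomial closed form,
#' used as an analytic oracle.
#'
#' @param scenario A [landscape_scenario()] (only the seed is used).
#' @param mode `"gaussian"` (default) or `"rectangular"`.
#' @param donor_peak,donor_width Donor band center and s.d. (nm).
#' @param acceptor_peak,acceptor_width Acceptor band center and s.d. (nm).
#' @param eps_max Acceptor peak extinction coefficient (M^-1 cm^-1).
#' @param rect_donor,rect_acceptor Wavelength intervals (nm) for
#'   rectangular mode.
#' @param grid Wavelength grid (nm).
#' @return List with `donor` and `acceptor` [spectrum()] objects; in
#'   rectangular mode also `J_analytic`, the closed-form overlap integral.
#' @export
gen_spectra <- function(scenario = landscape_scenario(),
                        mode = c("gaussian", "rectangular"),
                        donor_peak = 490, donor_width = 35,
                        acceptor_peak = 453, acceptor_width = 45,
                        eps_max = 32000,
                        rect_donor = c(490, 500), rect_acceptor = c(480, 510),
                        grid = seq(350, 650, by = 0.5)) {
  mode <- match.arg(mode)
  if (mode == "gaussian") {
    donor <- spectrum(grid, exp(-(grid - donor_peak)^2 / (2 * donor_width^2)),
                      "emission")
    acceptor <- spectrum(
      grid, eps_max * exp(-(grid - acceptor_peak)^2 / (2 * acceptor_width^2)),
      "extinction")
    return(list(donor = donor, acceptor = acceptor))
  }
  dlo <- rect_donor[1]; dhi <- rect_donor[2]
  donor <- spectrum(grid, ifelse(grid >= dlo & grid <= dhi, 1 / (dhi - dlo), 0),
                    "emission")
  acceptor <- spectrum(
    grid, ifelse(grid >= rect_acceptor[1] & grid <= rect_acceptor[2],
                 eps_max, 0), "extinction")
  lo <- max(dlo, rect_acceptor[1]); hi <- min(dhi, rect_acceptor[2])
  J_analytic <- if (lo < hi) {
    eps_max / (dhi - dlo) * (hi^5 - lo^5) / 5 * 1e-28
  } else 0
  list(donor = donor, acceptor = acceptor, J_analytic = J_analytic)
}
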