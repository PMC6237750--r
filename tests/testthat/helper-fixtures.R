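# Shared fixtures: small, fast scenarios built in code.

quiet_scenario <- function(...) {
  landscape_scenario(sigma_H = 0, sigma_C = 0, curve_noise = 0,
                     sf_noise = 0, cpmg_noise = 0, ...)
}

# thin a stopped-flow trace, keeping its concentration attributes
thin_trace <- function(tr, by = 5) {
  out <- tr[seq(1, nrow(tr), by = by), ]
  attributes(out)[c("E0", "D0", "dNTP")] <- attributes(tr)[c("E0", "D0", "dNTP")]
  out
}

# isolated two-state closing step used for analytic checks
two_state_scheme <- function(k3 = 124, km3 = 11.5) {
  kinetic_scheme(
    c("EDN", "cDN"),
    tibble::tibble(reactants = list("EDN", "cDN"),
                   products = list("cDN", "EDN"),
                   rate = c("k3", "km3")),
    c(k3 = k3, km3 = km3),
    tibble::tibble(species = c("EDN", "cDN"), E = c(1, 1))
  )
}
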