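# Forster resonance energy transfer: efficiency, spectral overlap, Forster
# radius and interprobe distance for the IAEDANS / dabcyl donor-quencher
# pair used to monitor fingers-domain closure.

#' FRET efficiency from donor quenching
#'
#' \eqn{E = 1 - F_{DA}/F_D}, where `F_DA` is donor emission in the
#' presence of the acceptor and `F_D` without it. Noise can push the raw
#' ratio outside \[0, 1\]; such values are returned as computed with a
#' warning rather than silently clipped.
#'
#' @param F_DA Donor emission with acceptor present (arbitrary units).
#' @param F_D Donor emission without acceptor, > 0.
#' @return Transfer efficiency (dimensionless).
#' @export
efret <- function(F_DA, F_D) {
  check_finite(F_DA, "F_DA")
  check_finite(F_D, "F_D")
  if (any(F_D <= 0)) abort("`F_D` must be > 0.")
  if (any(F_DA < 0)) abort("`F_DA` must be >= 0.")
  E <- 1 - F_DA / F_D
  if (any(E < 0 | E > 1)) {
    warn("FRET efficiency outside [0, 1]; returned unclipped (likely noise).")
  }
  E
}

#' Construct a validated spectrum
#'
#' @param wavelength_nm Strictly increasing wavelengths (nm).
#' @param value Emission intensity (arbitrary) or extinction coefficient
#'   (M^-1 cm^-1).
#' @param kind `"emission"` or `"extinction"`.
#' @return Tibble of class `spectrum` with a `kind` attribute.
#' @export
spectrum <- function(wavelength_nm, value, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  check_finite(wavelength_nm, "wavelength_nm")
  check_finite(value, "value")
  if (length(wavelength_nm) != length(value)) {
    abort("Wavelength and value must have equal length.")
  }
  if (any(wavelength_nm <= 0) || any(diff(wavelength_nm) <= 0)) {
    abort("Wavelengths must be positive and strictly increasing.")
  }
  if (kind == "emission" && any(value < 0)) {
    abort("Emission intensities must be >= 0.")
  }
  out <- tibble(wavelength_nm = wavelength_nm, value = value)
  attr(out, "kind") <- kind
  class(out) <- c("spectrum", class(out))
  out
}

#' Spectral overlap integral
#'
#' \eqn{J = \int E_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4 d\lambda}
#' over the common wavelength support, by the trapezoidal rule. The donor
#' emission is area-normalized before integration (set
#' `normalize = FALSE` to integrate raw intensities). Wavelengths are
#' supplied in nm and converted to cm internally, so with the extinction
#' coefficient in M^-1 cm^-1 the result carries M^-1 cm^3.
#'
#' @param donor_emission Donor emission [spectrum()] (or tibble with
#'   `wavelength_nm`, `value`).
#' @param acceptor_extinction Acceptor extinction [spectrum()]
#'   (M^-1 cm^-1).
#' @param normalize Area-normalize the donor emission first (default TRUE).
#' @return Overlap integral J in M^-1 cm^3.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction,
                             normalize = TRUE) {
  lo <- max(min(donor_emission$wavelength_nm),
            min(acceptor_extinction$wavelength_nm))
  hi <- min(max(donor_emission$wavelength_nm),
            max(acceptor_extinction$wavelength_nm))
  if (lo >= hi) abort("Donor and acceptor spectra have disjoint wavelength support.")
  grid <- sort(unique(c(
    donor_emission$wavelength_nm[donor_emission$wavelength_nm >= lo &
                                   donor_emission$wavelength_nm <= hi],
    acceptor_extinction$wavelength_nm[acceptor_extinction$wavelength_nm >= lo &
                                        acceptor_extinction$wavelength_nm <= hi],
    lo, hi)))
  ed <- stats::approx(donor_emission$wavelength_nm, donor_emission$value,
                      grid)$y
  ea <- stats::approx(acceptor_extinction$wavelength_nm,
                      acceptor_extinction$value, grid)$y
  if (normalize) {
    area <- pracma::trapz(donor_emission$wavelength_nm, donor_emission$value)
    if (area <= 0) abort("Donor emission has zero area; cannot normalize.")
    ed <- ed / area
  }
  # nm -> cm for both lambda^4 and the integration measure; the normalized
  # donor emission carries nm^-1, converted alongside
  nm_to_cm <- 1e-7
  scale <- if (normalize) nm_to_cm^4 else nm_to_cm^5
  pracma::trapz(grid, ed * ea * grid^4) * scale
}

#' Forster radius
#'
#' \eqn{R_0 = 9.78\times 10^3 (\kappa^2 \eta^{-4} f_d J)^{1/6}} in
#' Angstrom, with `J` in M^-1 cm^3. Defaults follow the IAEDANS/dabcyl
#' system: isotropic dynamic averaging (\eqn{\kappa^2 = 2/3}), refractive
#' index 1.344 (Tris buffer), donor quantum yield 0.7.
#'
#' @param J Overlap integral (M^-1 cm^3), > 0.
#' @param kappa2 Orientation factor (dimensionless, <= 4).
#' @param eta Refractive index of the medium.
#' @param f_d Donor quantum yield without acceptor.
#' @return Forster radius in Angstrom.
#' @export
forster_radius <- function(J, kappa2 = 2 / 3, eta = 1.344, f_d = 0.7) {
  vals <- c(J, kappa2, eta, f_d)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("J, kappa2, eta and f_d must all be finite and > 0.")
  }
  if (kappa2 > 4) abort("`kappa2` cannot exceed 4.")
  9.78e3 * (kappa2 * eta^-4 * f_d * J)^(1 / 6)
}

#' Interprobe distance from FRET efficiency
#'
#' Inverts \eqn{E = R_0^6 / (R_0^6 + r^6)} to
#' \eqn{r = R_0 ((1-E)/E)^{1/6}}. At `E = 0.5` the distance equals the
#' Forster radius.
#'
#' @param E Transfer efficiency, strictly inside (0, 1).
#' @param R0 Forster radius (Angstrom).
#' @return Distance in Angstrom.
#' @export
distance_from_efficiency <- function(E, R0 = 37.76) {
  check_finite(E, "E")
  if (any(E <= 0 | E >= 1)) {
    abort("`E` must lie strictly inside (0, 1); at 0 or 1 the distance is unbounded or zero.")
  }
  if (any(R0 <= 0)) abort("`R0` must be > 0.")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency at a given interprobe distance
#'
#' Forward form of the distance relation,
#' \eqn{E = R_0^6/(R_0^6 + r^6)}; exact inverse of
#' [distance_from_efficiency()].
#'
#' @param r Interprobe distance (Angstrom), > 0.
#' @param R0 Forster radius (Angstrom).
#' @return Transfer efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, R0 = 37.76) {
  if (any(r <= 0) || any(R0 <= 0)) abort("`r` and `R0` must be > 0.")
  R0^6 / (R0^6 + r^6)
}
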