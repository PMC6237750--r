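---
title: "Methods: the precatalytic conformational landscape of DNA polymerase β"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the precatalytic conformational landscape of DNA polymerase β}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polscape)
```

DNA polymerase β (pol β) fills single-nucleotide gaps during base-excision
repair. Before chemistry can occur, the enzyme moves through a series of
precatalytic conformational states: the DNA-bound binary complex binds a
dNTP to form an open ternary complex, the fingers subdomain closes around a
correct nascent base pair, and a further metal-dependent non-covalent
rearrangement precedes phosphodiester bond formation. Fidelity — the
enzyme's preference for the correct nucleotide — is determined to a large
degree by how these conformational equilibria respond to correct versus
incorrect base pairing. `polscape` implements the quantitative machinery
used to characterise this landscape from four complementary kinds of data:
methyl NMR chemical shifts, steady-state FRET, pre-steady-state kinetics
with stopped-flow fluorescence, and CPMG relaxation dispersion. A seeded
synthetic-data generator emulates each input so the entire pipeline is
testable without access to raw spectra.

## Chemical-shift vector analysis

ILV methyl resonances report on local conformation throughout the 335
residue enzyme. For a resonance observed in a reference "open" state
(binary complex) and a reference "closed" state (correct ternary complex),
the displacement from open to closed defines a per-residue *reference
vector* in the (¹H, ¹³C) shift plane. A test state's displacement from the
open position is then compared to this vector.

Two different carbon scalings serve two different purposes, and they are
deliberately kept apart:

* The **combined shift** `combined_shift()`,
  $\sqrt{(\Delta\delta_H^2 + \Delta\delta_C^2/4)/2}$, is used only for the
  significance filter: a resonance counts as shifted when its combined
  change is *strictly greater than* the threshold (0.025 ppm by default —
  1.5× the average replicate variability of the spectra;
  `significance_threshold()` recomputes this from replicate peak lists).
* All **vector geometry** — magnitude, the normalized magnitude
  $\Delta\delta_n$, and $\cos\theta$ — works in the scaled plane
  $(\Delta\delta_H,\, 0.2514\,\Delta\delta_C)$ via
  `shift_vector_magnitude()`, `normalized_magnitude()` and `cos_theta()`.

A significant resonance with $\cos\theta \ge 0.8$ is *on-pathway* toward
closure (only values strictly below 0.8 count as off-pathway, following
the literal rule); $\Delta\delta_n$ then measures how far along that
pathway it has moved (1 = fully closed). Closure of a whole state or
subdomain is summarised by the RMSD of $(\cos\theta, \Delta\delta_n)$
pairs from (1, 1) (`rmsd_one()`).

Numerical choices: reference vectors with magnitude ≤ 10⁻⁶ ppm are
degenerate — the ratio and angle are undefined there — and such rows are
excluded from RMSD and reported as `reference_degenerate`. The RMSD
denominator uses significant, non-degenerate rows (configurable to all
matched rows), and the reported average $\Delta\delta_n$ / $\cos\theta$
likewise average over significant rows only; the alternative readings are
exposed as options rather than silently chosen. Non-stereospecifically
assigned Leu/Val methyls appear as two independent rows. Two genuinely
open choices were resolved as follows: replicate variability for the
threshold is averaged within each enzyme group (with a `mode = "between"`
alternative), because replicate pairs of the *same* sample measure
measurement variability rather than a mutation effect; and subdomain
boundaries (lyase 1–87, thumb 88–151, palm 152–262, fingers 263–335) are
package defaults chosen to place the catalytic aspartates in the palm and
the I277/R283 region in the fingers — they are fully configurable.

```{r}
scen <- landscape_scenario(closure_fraction = 0.5, sigma_H = 0,
                           sigma_C = 0, seed = 1)
sc <- gen_peak_lists(scen)
cmp <- compare_states(sc$test, sc$open, sc$closed)
glance(cmp)
```

A half-closed noise-free synthetic state recovers $\Delta\delta_n = 0.5$
and $\cos\theta = 1$ exactly; constructed off-pathway peaks (displaced
orthogonally in the scaled plane) classify as off-pathway with
$\cos\theta \approx 0$.

## Pre-steady-state kinetics and fidelity

Burst experiments (enzyme-DNA mixed with dNTP) follow the biphasic model

$$[P](t) = E_\mathrm{app}\left[\left(\tfrac{k_\mathrm{obs}}{k_\mathrm{obs}+k_\mathrm{ss}}\right)^2(1-e^{-(k_\mathrm{obs}+k_\mathrm{ss})t}) + \tfrac{k_\mathrm{obs}k_\mathrm{ss}}{k_\mathrm{obs}+k_\mathrm{ss}}t\right].$$

The squared amplitude ratio is the standard form: it is dimensionally
consistent and gives the correct $E_\mathrm{app}$ amplitude as
$k_\mathrm{ss}\to 0$. A variant of this equation circulates in print with
a first-power numerator; `burst_model(form = "as_printed")` reproduces
that literal form for comparison, but we treat it as a transcription
artifact and default to the standard form.

Single-turnover curves are single exponentials; their observed rates
follow the hyperbolic saturation law
$k_\mathrm{obs} = k_\mathrm{pol}[\mathrm{dNTP}]/(K_d + [\mathrm{dNTP}])$.
All fits are unweighted nonlinear least squares (no weights are specified
for the source data; `weights` arguments exist) with multi-start
initialisation from log-spaced rate grids, so no user tuning is needed to
avoid local minima. Degenerate inputs are flagged rather than fit: a
progress curve with no resolvable burst phase sets `degenerate = TRUE`,
and a titration that does not span $K_d$ raises an ill-conditioning
warning.

Fidelity arithmetic (`fidelity_metrics()`, `fidelity_table()`): catalytic
efficiency is $k_\mathrm{pol}/K_d$ (µM⁻¹s⁻¹), and
fidelity = (correct efficiency + incorrect efficiency)/incorrect
efficiency. Published tables typically round efficiencies to two
significant figures before forming the quotient; the default
`rounding = "as_printed"` reproduces that convention and
`rounding = "none"` keeps full precision. The two modes differ by well
under 1% here, which is within the tolerance used everywhere fidelity is
compared.

```{r}
fidelity_metrics(c(k_pol = 12.0, K_d = 1.5), c(k_pol = 0.134, K_d = 365))
```

## FRET distances

With a donor (IAEDANS on V303C) quenched by an acceptor (dabcyl on the
DNA), efficiency is $E = 1 - F_{DA}/F_D$ and distance follows
$r = R_0((1-E)/E)^{1/6}$. The Förster radius is
$R_0 = 9.78\times10^3(\kappa^2\eta^{-4}f_d J)^{1/6}$ Å with $J$ in
M⁻¹cm³; defaults are $\kappa^2 = 2/3$ (dynamic isotropic averaging),
$\eta = 1.344$ and $f_d = 0.7$, giving $R_0 = 37.76$ Å for
$J \approx 2.3\times10^{-14}$ M⁻¹cm³. The overlap integral
$J = \int E_D(\lambda)\varepsilon_A(\lambda)\lambda^4 d\lambda$
area-normalizes the donor emission before integrating (raw mode
available) and converts wavelength grids from nm to cm internally so the
units come out as M⁻¹cm³. Efficiencies that fall outside [0, 1] through
noise are reported with a warning, never silently clipped, since clipping
would bias distance estimates near the extremes.

## The incorporation mechanism and its constrained global fit

The scheme in `polb_scheme()` runs
E + D ⇌ ED, ED + N ⇌ EDN, EDN ⇌ cDN (fingers closing),
cDN ⇌ nDN (metal-dependent non-covalent step), nDN → EP (chemistry), and
a lumped reversible product-release step. Simulation
(`simulate_scheme()`) integrates the mass-action ODEs with a stiff solver
at relative tolerance 10⁻⁸ — the rate constants span four orders of
magnitude — and asserts conservation of the enzyme, DNA and nucleotide
moieties at every output time.

The fitting strategy mirrors how such schemes are constrained against
independent measurements rather than fit freely: DNA binding is fixed
through $k_{-1}/k_{+1} = K_d(\mathrm{DNA})$; dNTP binding is an
equilibrium constraint, implemented as diffusion-scale association
(100 µM⁻¹s⁻¹) with dissociation $= K_d \times$ association (a modeling
convention, flagged as such); chemistry is fixed to the measured
$k_\mathrm{pol}$ with its reverse set to zero; and the reverse
conformational rates $k_{-3}$, $k_{-4}$ come from the trap experiment.
Only the forward conformational rates (`k3`, `k4`) are free by default.
Per-trace fluorescence amplitudes enter the observable linearly and are
profiled out by least squares at every optimizer step, which keeps the
nonlinear problem two-dimensional. Points inside the 2 ms instrument dead
time are removed before fitting (`dead_time_mask()`, with an optional
artifact-subtraction hook).

The trap experiment — a pre-formed closed ternary complex mixed with
excess unlabeled enzyme-DNA that sequesters released dNTP — relaxes
through $k_{-4}$, then $k_{-3}$, then dNTP release, and its fluorescence
fits a triple exponential (`fit_triple_exponential()`). One- and
two-exponential alternatives are compared by AIC; rates are assigned to
steps in order (fastest ↔ reverse non-covalent), and near-equal adjacent
rates set an `ambiguous` flag instead of being silently resolved. Release
is governed by the dNTP binding equilibrium by default, with a free-rate
option, since the source protocol constrains that step through the
measured $K_d$. Rates not quoted in the source text (the forward
non-covalent rate, product release) carry documented placeholder defaults
(20 s⁻¹; 10 s⁻¹ and 0.1 µM⁻¹s⁻¹) — they are study-condition inputs, not
fitted results.

## CPMG dispersion and the flexibility rule

Millisecond exchange adds
$R_\mathrm{ex}[1 - 2\tanh(k_\mathrm{ex}\tau_{cp}/2)/(k_\mathrm{ex}\tau_{cp})]$
to the effective transverse relaxation rate, with
$R_\mathrm{ex} = p_a p_b \Delta\omega^2/k_\mathrm{ex}$ in the
fast-exchange limit ($\Delta\omega$ in rad s⁻¹). A residue is *flexible*
when (i) the dispersive model is preferred over a flat line and (ii)
$R_\mathrm{ex} > 2$ s⁻¹. "Preferred" is operationalized as a nested-model
F-test at α = 0.05 (the flat model, one parameter, inside the dispersive
model, three), with AIC as an alternative criterion — the original rule
names no statistic, so the package makes the choice explicit and
configurable. Fits are per-residue and independent; no global
$k_\mathrm{ex}$ is imposed, since flexibility is reported per residue.
Under a flat null with realistic noise (0.2 s⁻¹) the false-positive rate
of the combined rule stays well below 5%: the $R_\mathrm{ex} > 2$
condition is rarely met by noise even when the F-test fires.

## What the synthetic generator does and does not emulate

`landscape_scenario()` fixes the study conditions: reference peak sets in
realistic ILV ranges (¹H 0–1.5 ppm, ¹³C 9–27 ppm) with open→closed
vector magnitudes of 0.03–0.2 ppm; a test state at closure fraction 0.5
with four off-pathway resonances (the partially closed regime observed
for the mutator binary complex); wild-type burst (9, 1.2 s⁻¹) and
single-turnover ($k_\mathrm{pol}$ = 12 s⁻¹, $K_d$ = 1.5 µM, dNTP titrated
0.5–1500 µM) parameters; stopped-flow traces from the wild-type scheme
(fingers closing 124/11.5 s⁻¹) with a 2 ms dead time; trap relaxation at
(163, 48.2, 5) s⁻¹; and a 40-residue CPMG panel with 14 dispersive
members sampled at 1/τ_cp from 25 to 2000 s⁻¹ — a grid chosen to bracket
the ~1500 s⁻¹ exchange regime it must characterise, as an experimentalist
would. Off-pathway peaks are constructed *exactly orthogonal* to the
reference vector in the scaled plane, so their intended class is known
analytically rather than approximately.

The generators reproduce the statistical structure the analyses assume —
they do not simulate raw FIDs, spectral artifacts, baseline drift,
photobleaching, or gel quantification error. Passing the round-trip
suites therefore demonstrates correctness of the estimators under their
own model assumptions, not robustness to every artifact of real data.

Problem sizes used in the validation suites — 60-peak lists, traces of a
few hundred points, 50-replicate noise ensembles, 1000-replicate null
calibration — are the package's own choices for a thorough desk-scale
validation; all scale up linearly if larger ensembles are wanted.

## Known limitations

* The CPMG model is the fast-exchange limit only; slow-to-intermediate
  exchange (full two-site expressions) is out of scope.
* The dispersion F-test is approximate at parameter boundaries
  ($R_\mathrm{ex} \ge 0$), which makes the flexibility call conservative.
* The kinetic scheme lumps product release into one reversible step;
  rates beyond the quoted set are placeholders, so simulated late-time
  behaviour should not be over-interpreted.
* FRET distances inherit the usual $\kappa^2 = 2/3$ assumption; no
  anisotropy-based correction is attempted.
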