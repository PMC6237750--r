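# polscape

Quantitative analysis of the precatalytic conformational landscape of DNA
polymerase β (pol β), the gap-filling polymerase of base-excision repair.
Pol β selects the correct nucleotide through a cascade of conformational
states — open binary complex, open ternary complex, closed ternary complex
(fingers closing), and a metal-dependent non-covalent rearrangement — and
perturbations of this landscape (e.g. the I260Q hinge mutator) degrade
fidelity. `polscape` is aimed at enzymologists and NMR spectroscopists who
want to quantify that landscape from standard experiments. It implements:

* **Chemical-shift vector analysis** of ILV methyl peak lists: each test
  resonance is compared to the open→closed reference vector in the scaled
  plane (Δδ_H, 0.2514·Δδ_C). A combined shift
  √((Δδ_H² + Δδ_C²/4)/2) > 0.025 ppm marks a significant change;
  cos θ ≥ 0.8 marks it on-pathway toward closure; Δδ_n (vector-magnitude
  ratio) measures how far closure has progressed; closure per state or
  subdomain is RMSD of (cos θ, Δδ_n) from (1, 1).
* **Pre-steady-state kinetics**: biphasic burst fits, single-turnover
  exponential and hyperbolic saturation fits for k_pol and K_d(dNTP), and
  the fidelity table — efficiency = k_pol/K_d, fidelity =
  (eff_correct + eff_incorrect)/eff_incorrect, fold differences between
  enzymes.
* **FRET**: transfer efficiency E = 1 − F_DA/F_D, overlap integral
  J = ∫E_D(λ)ε_A(λ)λ⁴dλ, Förster radius
  R₀ = 9.78×10³(κ²η⁻⁴f_d·J)^{1/6} Å, and interprobe distance
  r = R₀((1−E)/E)^{1/6}.
* **Mechanism fitting**: stiff mass-action simulation of the multi-step
  incorporation scheme, constrained global fitting of stopped-flow FRET
  dNTP series (binding equilibria, chemistry and trap-measured reverse
  rates fixed; forward conformational rates free; per-trace amplitudes
  profiled out linearly), and the triple-exponential trap-experiment
  model for the reverse rates.
* **CPMG relaxation dispersion**: fast-exchange fits
  R₂(1/τ_cp) = R₂⁰ + R_ex[1 − 2tanh(k_ex·τ_cp/2)/(k_ex·τ_cp)] with an
  F-test against a flat line and the flexibility rule R_ex > 2 s⁻¹.
* A **seeded synthetic-data generator** for every input, with ground
  truth retained, so the full pipeline is testable end to end.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(polscape)

# a half-closed test state with 4 off-pathway resonances, seeded
scen <- landscape_scenario(closure_fraction = 0.5, seed = 7)
sc   <- gen_peak_lists(scen)
cmp  <- compare_states(sc$test, sc$open, sc$closed)
cmp
#> State comparison: synthetic_test vs open = open_reference / closed = closed_reference
#>   60 matched peaks: 45 on-pathway, 4 off-pathway, 11 not significant, 0 degenerate
#>   RMSD_1.0 global: 0.563  mean delta_n: 0.524  mean cos theta: 0.918
```

The mean Δδ_n of 0.52 recovers the planted closure fraction of 0.5: the
state has moved about halfway along the open→closed pathway, and the four
orthogonally perturbed resonances are flagged off-pathway. (Peak-position
noise pushes a few small reference vectors below the significance
threshold and pulls the mean cos θ below 1.)

```r
# fidelity of wild-type pol β on template G (correct dC vs incorrect dA)
fidelity_metrics(c(k_pol = 12.0, K_d = 1.5), c(k_pol = 0.134, K_d = 365))
#> # A tibble: 1 × 5
#>   D_kpol  D_Kd efficiency_correct efficiency_incorrect fidelity
#>    <dbl> <dbl>              <dbl>                <dbl>    <dbl>
#> 1   89.6  243.                  8             0.000367   21623.

# FRET distance at 35% transfer efficiency
distance_from_efficiency(0.35, R0 = 37.76)
#> [1] 41.86
```

The wild-type enzyme is ~21,600-fold more efficient with the correct
nucleotide; discrimination comes mostly from ground-state binding (243×)
rather than the incorporation rate (90×).

A command-line front end is installed at `inst/exec/landscape`
(subcommands `synth`, `shiftvec`, `kinetics`, `fret`, `cpmg`, `run`).

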