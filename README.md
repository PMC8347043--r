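# glassprobe

Multi-probe detection of the glass transition in low-moisture starch-based
biopolymers (dry pasta, extruded flours), for food-physics and biopolymer
researchers who want the full analysis chain — from raw experimental curves
to a consolidated transition report — as tested, reusable R functions.

The package combines three experimental probes of the same physical event:

1. **Time-domain ¹H NMR relaxometry.** Each free induction decay is
   decomposed into solid-like and mobile proton components by two nested
   models,

   F₁(t) = Sₛ·exp(−(t/T₂ₛ\*)²)·sin(bt)/(bt) + L·exp(−t/T₂L\*)

   F₂(t) = S_g·exp(−(t/T₂g\*)²) + Sₛ·exp(−(t/T₂ₛ\*)²)·sin(bt)/(bt) + L·exp(−t/T₂L\*)

   fitted by bounded Levenberg–Marquardt and explored by a Metropolis
   sampler of the χ² landscape (likelihood e^(−χ²/2)), which yields
   parameter probability distributions and model selection by minimal χ².
   Discontinuities in the fitted parameters across temperature bracket the
   transition.

2. **Calorimetric plasticization.** Tg-versus-water-content data are fitted
   by the Gordon–Taylor mixing rule
   Tg(X_w) = (X_s·Tgs + k·X_w·Tgw)/(X_s + k·X_w) with the water glass
   transition fixed at −135 °C.

3. **Epithermal neutron methods.** Mass density versus temperature is
   estimated two independent ways — from the epithermal transmission
   plateau (scattering power s = −ln T̄ ∝ number density) and from the
   incoherent diffraction background — each calibrated at the lowest
   temperature to the tabulated starch density of 1.3 g/cm³. An additive
   functional-group model (CH₂, CH, OH, water OH plus heavy atoms, each a
   Doppler-broadened free gas at its harmonic effective temperature)
   predicts total neutron cross-section curves and hydrogen
   momentum-distribution widths; neutron Compton scattering spectra are
   fitted detector-by-detector by variable projection (kinematically fixed
   peak centres, nonnegative linear intensities, nonlinear widths).

A first-class synthetic-data module generates every input (FIDs, Tg-vs-water
points, transmission curves, diffraction patterns, TOF spectra) from known
ground truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(glassprobe)
report <- run_pipeline(run_config(seed = 1))
print(report)
```

```
Multi-probe glass-transition report (seed 1)
  DSC/Gordon-Taylor: Tgs = 112.0 degC, k = 2.40 (R2 = 0.999)
  NMR step window:   40-45 degC
  Density (transmission) window: 40-60 degC
  Density (diffraction)  window: 40-60 degC
```

Reading the output: the Gordon–Taylor refit of the synthetic calorimetric
stage recovers a dry-matter glass transition Tgs ≈ 112 °C and curvature
k ≈ 2.4; the NMR parameter scan flags a concerted discontinuity of the
solid-component parameters between the measured temperatures 40 and 45 °C;
and both calibrated densitometers bracket the density drop of the 1.3 →
1.1 g/cm³ schedule between the measured temperatures 40 and 60 °C. The two
windows differ because the probes answer different questions on different
temperature grids — both are reported, neither is interpolated.

Individual stages are ordinary functions, e.g.

```r
st <- build_stoichiometry(moisture_value(0.1069, "wet"))
print(st)
#> C6 H12.15 O6.077  (nu = 1.077, M = 181.55 g/mol)
sigma_free_total(st)
#> [1] 300.1553   # barns per formula unit, the epithermal plateau value
```

A thin command-line wrapper lives at `inst/cli/glassprobe.R`
(`Rscript inst/cli/glassprobe.R report --seed 1 --out out/`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the models, their
assumptions, every tunable constant with units and rationale, what the
synthetic generators do and do not emulate, and known limitations.
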