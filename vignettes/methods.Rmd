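---
title: "Models and methods behind glassprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glassprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassprobe)
```

# The problem

Low-moisture starch products (dry pasta, extruded flours) are amorphous
glasses at room temperature. On heating, or on water uptake, they cross the
glass transition into a rubbery state: molecular mobility rises sharply,
density drops, and texture and stability change. Because the transition in a
heterogeneous food matrix is broad and technique-dependent, it is best
located by combining probes that see different observables. `glassprobe`
implements three such probes as one reusable pipeline, together with a
synthetic-data module that generates every input from known ground truth so
the whole chain is testable by parameter recovery:

1. **Time-domain proton NMR relaxometry** — decomposition of the free
   induction decay (FID) into solid-like and mobile proton components, with
   Bayesian chi-square model selection between two candidate decompositions.
2. **Calorimetric plasticization analysis** — the Gordon–Taylor mixing rule
   fitted to glass-transition temperature versus water content.
3. **Epithermal neutron methods** — mass densitometry from the neutron
   transmission plateau and from the incoherent diffraction background; an
   additive functional-group forward model of the total neutron
   cross-section; and neutron Compton scattering (NCS) fitting of nuclear
   momentum distributions (NMDs) by variable projection.

# FID relaxation models

Two nested models are fitted to each FID $F(t)$:

$$F_1(t) = S_s\,e^{-(t/T_{2s}^*)^2}\,\frac{\sin bt}{bt} + L\,e^{-t/T_{2L}^*},$$
$$F_2(t) = S_g\,e^{-(t/T_{2g}^*)^2} + S_s\,e^{-(t/T_{2s}^*)^2}\,\frac{\sin bt}{bt} + L\,e^{-t/T_{2L}^*}.$$

The Abragam term (amplitude $S_s$) describes strongly dipolar-coupled,
semi-crystalline protons; the Gaussian term ($S_g$, model 2 only) a second,
amorphous solid fraction; the exponential ($L$) mobile protons. The Gaussian
exponent deliberately carries no factor $\tfrac12$. The sinc factor is
evaluated by its series for $|bt| < 10^{-8}$ so the model is continuous at
$t = 0$ and $b = 0$. Second moments are
$M_2^{\mathrm{abr}} = 2/T_{2s}^{*2} + b^2/3$ and
$M_2^{\mathrm{gau}} = 2/T_{2g}^{*2}$ (curvature $-F''(0)/F(0)$ of the unit
component).

Fitting minimises $\chi^2 = \sum_i ((y_i - F(t_i))/\sigma_i)^2$ by bounded
Levenberg–Marquardt (`minpack.lm`). When no starting point is given, a small
multi-start is run: the mobile component is initialised by a log-linear tail
regression, and the fast amplitude is split over a coarse grid of
$(S_g:S_s)$ ratios, decay times and beat rates; the best $\chi^2$ solution
wins. A floor $b \ge 10^{-3}$ rad/µs keeps the Abragam label attached to
the oscillating component, preventing component swapping across a
temperature series. No leading points are masked by default (a receiver
dead-time mask is configurable through the bounds/init arguments).

**Identifiability and the synthetic ground truth.** The default synthetic
truth at 25 °C is $S_g = 0.5$, $T_{2g}^* = 12$ µs, $S_s = 0.13$,
$T_{2s}^* = 25$ µs, $b = 0.45$ rad/µs, $L = 0.37$, $T_{2L}^* = 400$ µs
(amplitudes sum to 1, so amplitudes double as fractions). These constants
were chosen once, by a design simulation, so that the two solid components
are distinguishable at the 0.5% noise level used in the recovery tests: the
Gaussian must decay faster than the Abragam envelope and the dipolar beat
must be pronounced, otherwise the two components are nearly collinear
(correlation above 0.93) and no fitting method can separate their
amplitudes. Even in the identifiable setting, $T_{2s}^*$ and $b$ remain
cross-correlated — they act as one "eigen-parameter" of the Abragam shape —
so recovery of the pair is assessed through the identifiable combination
$M_2^{\mathrm{abr}}$, while $T_{2s}^*$ alone scatters at the ~15% level.

# Bayesian chi-square model selection

`metropolis_chain()` samples the likelihood $\exp(-\chi^2/2)$ by random-walk
Metropolis with Gaussian proposals; out-of-bounds proposals are rejected.
Default proposal scales are 2% of each parameter's (capped) bound range and
are adapted towards ~30% acceptance during burn-in only, in windows of 50
steps with the adaptation factor clipped to $[1/3, 3]$; the retained chain
is therefore a fixed-kernel Metropolis sample. The burn-in default is 20% of
the chain. Chains are reproducible bit-for-bit from their seed.

Model selection (`model_compare()`) uses the minimal $\chi^2$ of each chain,
reporting the histogram mode of the $\chi^2$ distribution alongside; ties go
to the model with fewer parameters. No information criterion is layered on
top. The chain carries a checksum of its data, so chains from different
signals refuse comparison. The sampler's correctness is tested against the
conjugate closed form for a linear model with known noise, where the
posterior is exactly Gaussian.

# Gordon–Taylor plasticization

$$T_g(X_w) = \frac{X_s T_{gs} + k X_w T_{gw}}{X_s + k X_w}, \qquad X_s = 1 - X_w,$$

with $X_w$ the wet-basis water mass fraction. $T_{gw}$ is treated as a
literature constant (−135 °C) and held fixed; $(T_{gs}, k)$ are estimated by
Levenberg–Marquardt. Moisture values are carried with an explicit basis
(`moisture_value()`), because food-science moisture is conventionally quoted
per gram of dry matter while the mixing rule wants a mass fraction; the
round trip $w = m/(1+m)$, $m = w/(1-w)$ is exact. A dataset with no
water-content signal collapses $k$ to its lower bound and is flagged rather
than reported as a fit. Note that quoting a transition near 55 °C for a
moisture of 0.1069 g/g d.m. depends on which basis is inserted into the
formula: the wet-basis reading gives 57.2 °C with the default parameters and
the dry-basis reading gives a higher value; the package always states its
convention and does not force agreement with rounded literature values.

# Neutron stoichiometry and the functional-group cross-section model

The sample is modelled as a hydrated anhydroglucose polymer
$\mathrm{C_6H_{10}O_5}\,(\mathrm{H_2O})_\nu$ with
$\nu = m_{\mathrm{dm}} \cdot M_{\mathrm{C_6H_{10}O_5}}/M_{\mathrm{H_2O}}$
computed from the dry-matter moisture $m_{\mathrm{dm}}$; protein, fat and
ash are neglected. A wet-basis moisture of 0.1069 gives $\nu = 1.077$,
i.e. a 1.1-hydrate after one-decimal rounding (the dry-basis reading would
give $\nu \approx 0.96$; the wet-basis convention is the default because it
reproduces the printed hydrate stoichiometry).

The total cross-section per formula unit is an additive sum over
functional groups — CH₂ (2 H), CH (5 H), matrix OH (3 H), water OH
($2\nu$ H) — plus heavy-atom pseudo-groups. Each group contributes a
Doppler-broadened free-gas cross-section evaluated at the group's harmonic
**effective temperature**

$$T^* = \frac{\sum_i w_i\,\frac{\hbar\omega_i}{2k_B}\coth\frac{\hbar\omega_i}{2k_BT}}{\sum_i w_i},
\qquad
\sigma(E) = \sigma_{\mathrm{free}}\left[\Big(1+\tfrac{1}{2x^2}\Big)\operatorname{erf}(x) + \frac{e^{-x^2}}{x\sqrt{\pi}}\right],
\quad x^2 = \frac{A E}{k_B T^*},$$

with $\sigma_{\mathrm{free}} = \sigma_b (A/(A+1))^2$ the free-atom value and
$A$ the atom-to-neutron mass ratio. This form keeps the three properties the
analysis relies on: additive group structure, the exact epithermal plateau
$\Sigma_{\mathrm{free}}$ (reached to <0.5% above 50 eV), and a thermal
region sensitive to the vibrational mode energies through $T^*$. It is a
self-contained harmonic free-gas construction, not a reproduction of any
published group parametrisation. Default mode-energy triplets (meV, one
mode per momentum direction) are CH₂ {360, 175, 90}, CH {360, 160, 100},
OH and water OH {420, 200, 80} — representative stretch/bend/torsion
frequencies of organic hydrogen — and low-lying skeletal modes for C, O and
Al. Only qualitative temperature trends are asserted for the thermal region;
the bound cross-sections (H 82.02, C 5.551, O 4.232, Al 1.503 b) are
standard table values.

The same harmonic modes predict the hydrogen NMD width,
$$\sigma_y^2 = \frac{1}{3}\sum_i w_i\,\frac{A\,\hbar\omega_i}{2\,(\hbar^2/m_n)}\coth\frac{\hbar\omega_i}{2k_BT},$$
with $\hbar^2/m_n = 4.1434$ meV Å². Because the dominant modes lie far above
$k_BT$ in the −20…80 °C range, the predicted width is flat to better than 2%
across that range — the reference line against which fitted NCS widths are
compared. Per-group widths are combined across hydrogen sites by
count-weighted averaging of variances (the observed distribution is the
mixture of site distributions).

# Densitometry

**Transmission.** The epithermal plateau obeys
$T(E) = e^{-n_{\mathrm{fu}} d\,\Sigma_{\mathrm{free}}}$, so the scattering
power $s = -\ln \bar T$ over the default [10, 100] eV window is proportional
to number density. A single-point calibration at the lowest temperature
(−20 °C pinned to 1.3 g/cm³, the tabulated density of starch at this water
content) converts the series to mass densities:
$\rho(T) = \rho_{\mathrm{ref}}\, s(T)/s(T_{\mathrm{ref}})$. The plateau is
flat only to ~2–3 × 10⁻⁵ in relative terms (the Doppler correction retains a
weak $T^*$ dependence), which sets the floor on the agreement between
noise-free estimators — a physical effect, not a numerical artefact.

**Diffraction.** The only Bragg peaks in the pattern come from the fcc
aluminium container (lattice constant 4.0495 Å, reflections at
$d = a/\sqrt{h^2+k^2+l^2}$ for all-even/all-odd $hkl$); the sample itself is
amorphous and contributes a flat incoherent background proportional to its
number density. The background is integrated over a d-spacing window
(default [2.5, 3.5] Å) that the code verifies to be at least three peak
widths clear of every allowed aluminium reflection — a violating window is
rejected with the offending $(hkl)$ named — and calibrated the same way.

**Transition bracketing.** The transition window is reported as the two
*measured* temperatures bracketing the contiguous run of inter-point drops
around the largest drop exceeding 3× the median absolute inter-point change;
nothing is interpolated. On the six-temperature grid with the default
sigmoid schedule (1.3 → 1.1 g/cm³, midpoint 50 °C, width 5 °C) this yields
(40, 60) °C. A strictly linear series returns a none-found flag. The same
rule, applied two-sidedly, scans fitted NMR parameter series for
discontinuities.

# Neutron Compton scattering

On an inverse-geometry spectrometer the final energy is fixed
($E_1 = 4897$ meV by default, flight paths $L_0 = 11$ m, $L_1 = 0.7$ m —
configurable instrument constants) and spectra are recorded in time of
flight, $t = L_0/v_0 + L_1/v_1$ with $v = 437.39\sqrt{E\,[\mathrm{meV}]}$
m/s. The recoil peak of a nucleus of mass ratio $A$ sits at the incident
energy solving $E_0 - E_1 = \hbar^2 q^2/2M$; for $A = 1$ this reduces to
$E_0 = E_1/\cos^2\theta$, which has no solution for $\theta \ge 90°$ —
hydrogen is visible only to forward-scattering detectors, and the fitter
enforces this exclusion automatically.

Peak shapes in TOF are Gaussians obtained by mapping the y-space Gaussian
NMD through the local Jacobian $|dy/dt|$, with the detector resolution width
added in quadrature; full resolution-function convolution is out of scope.
The per-detector fit is a **variable projection**: peak centres are fixed by
kinematics; for each trial width vector the intensities (and a flat
baseline) are solved by nonnegative linear least squares
(`pracma::lsqnonneg` — nonnegativity reflects physical counts), and an outer
bounded quasi-Newton search optimises only the widths. Across detectors, a
self-consistent loop averages widths (inverse-residual weights), restarts
each detector from the average, and stops when widths change by less than
$10^{-4}$ relative (at most 10 iterations). Relative intensities are
averaged over detectors that see the full mass set and renormalised to sum
to one. The y-transform maps each TOF bin to
$y = (M/\hbar q)(\omega - \hbar q^2/2M)$ with Jacobian-corrected,
unit-normalised intensities.

# What the synthetic generators do and do not emulate

The generators reproduce the statistical structure the analyses assume:
exact model curves at zero noise, additive Gaussian noise for FID,
transmission and diffraction, $\sqrt{\mathrm{counts}}$-scaled Gaussian noise
for TOF spectra, and full seed reproducibility. They do **not** emulate
instrument resolution functions beyond a single width parameter per
detector, multiple scattering, gamma backgrounds, detector efficiency
variation, beam-profile effects, or sorption/desorption physics. Passing
recovery tests therefore demonstrates the correctness and statistical
efficiency of the estimators under the stated noise models — not robustness
to every systematic effect present in real instrument data. Sample thickness
defaults to 0.3 cm (configurable); FID noise defaults are expressed as a
fraction of total amplitude because instrument noise figures are
scenario-specific.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: 20 noise
realizations per recovery experiment; 2048-point FIDs; 400-point
logarithmic energy grids over 1 meV–1000 eV; six-temperature neutron
series; MCMC chains of 1.5–50 k steps depending on the check. Tolerances
follow the quantity: machine-level for arithmetic identities and round
trips, percent-level for Doppler/plateau asymptotics, and
sampling-limited (10–20%) for Monte-Carlo posterior summaries. Degenerate
inputs (all-zero amplitudes, constant-Tg datasets, windows touching Bragg
peaks, unreachable kinematics) raise informative errors rather than
returning numbers.

# Known limitations

- The functional-group cross-section model is harmonic and incoherent; it
  cannot describe coherent/Bragg contributions, resonance absorption, or
  anharmonic softening except through user-supplied mode changes.
- Density estimates are relative to the single calibration point; absolute
  densitometry is out of scope.
- The FID decomposition inherits the $T_{2s}^*$–$b$ degeneracy discussed
  above; single-parameter error bars for these two should be read with the
  covariance in mind.
- NCS peak shapes ignore the asymmetric instrument resolution of real
  inverse-geometry spectrometers; fitted widths are exact only with respect
  to the generator's own peak model.
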