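---
title: "Broad-beam shielding methods in nmshield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Broad-beam shielding methods in nmshield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmshield)
```

## The problem

Photons emitted by a nuclear medicine patient are uncollimated, so any
barrier between the patient and a point of concern operates in broad-beam
geometry: besides the unscattered component `exp(-mu*x)`, photons scattered
by the barrier itself, the air and nearby structures also reach the point
of concern. The transmission is therefore `T(x) = B(x) * exp(-mu*x)` with a
buildup factor `B >= 1` that depends on energy, material, thickness and the
surrounding geometry. Narrow-beam attenuation data alone under-predicts the
shielding needed.

nmshield packages a practical treatment of this problem for the four
radionuclides that dominate diagnostic and theranostic practice (Tc-99m,
F-18, I-131, Lu-177) and six barrier materials.

## The Archer transmission model

Broad-beam transmission as a function of thickness `x` (mm) is represented
by the three-parameter Archer form

$$T(x) = \left[\left(1 + \tfrac{\beta}{\alpha}\right)e^{\alpha\gamma x}
          - \tfrac{\beta}{\alpha}\right]^{-1/\gamma}$$

which satisfies `T(0) = 1`, decreases strictly, and approaches
`exp(-alpha*x)` at depth — `alpha` (1/mm) is the asymptotic attenuation
coefficient once the spectrum has hardened, `beta` (1/mm) shapes the
low-thickness shoulder (negative `beta` produces the concave shoulder of
buildup-dominated curves), and `gamma` controls how fast the asymptote is
reached. The closed-form inverse

$$x(T) = \frac{1}{\alpha\gamma}\,
  \ln\!\frac{T^{-\gamma} + \beta/\alpha}{1 + \beta/\alpha}$$

turns a required transmission directly into a required thickness; the
package evaluates both with log-space guards so that extreme arguments
(e.g. `gamma` near 30, `T` near 1e-4) neither overflow nor lose precision,
and round-trips `transmission(thickness(T)) = T` to better than 1e-10
relative error. Out-of-domain inputs (negative thickness, `T` outside
(0, 1]) raise errors rather than clamping, so misuse is visible.

Fitted `(alpha, beta, gamma)` triples for 21 nuclide–material pairs are
shipped as package data, along with each nuclide's exposure-rate constant
`Gamma` (R·cm²/(mCi·h) at 1 cm), f-factor (cGy/R), half-life and dominant
photon lines, material densities/compositions, and recommended occupancy
factors. Gypsum rows for F-18 and I-131 are deliberately absent: in
practical thicknesses gypsum barely attenuates their photons and no
parameters exist for those pairs. Lead itself is not part of the published
material-composition table; the package adds pure Pb at 11.35 g/cm³ and
flags it (`source = "added"`).

## The design chain

`solve_barrier()` implements the standard shielding-design arithmetic:

* weekly workload `W` (mCi·h/week), optionally decay-corrected by the
  session-averaged factor `(1 - exp(-lambda*t))/(lambda*t)`. The default is
  *no* decay correction — the conservative convention for short residence
  times relative to half-life;
* unshielded weekly dose `D = W * Gamma * f / d²` (µGy/week) at distance
  `d` cm, taken as the straight line from source centre to the point of
  concern (barrier obliquity ignored);
* required transmission `T = P / (O * D)` for weekly limit `P` and
  occupancy factor `O`, capped at 1;
* required thickness from the inverse Archer equation.

Dose is reported in µGy/week and treated as numerically equal to µSv/week
for these photon emitters (a deep-dose-equivalent surrogate). Activities in
GBq convert at exactly 37 MBq/mCi. When the required transmission falls
below 0.01 the solver warns: at such transmissions, scatter over the
barrier off the ceiling and floor dominates the residual dose and further
thickening of the barrier is futile; an over-barrier baffle is the
appropriate fix, not more lead.

`composite_transmission()` multiplies per-layer Archer transmissions. This
deliberately ignores inter-layer spectral hardening — the tests demonstrate
the size of that approximation rather than hide it.

## Curve fitting and identifiability

`fit_archer()` fits the Archer form to (thickness, transmission) data by
Levenberg–Marquardt least squares **on ln T**: transmission data span
several decades, and linear-space fitting would let the first few points
dominate. `alpha` and `gamma` stay positive through a log parameterization;
`beta` is unconstrained but penalized outside the valid region
`beta > -alpha`. Five deterministic multi-starts (a slope-based heuristic
plus a spread of `gamma` starting values) guard against the model's known
multi-modality, and ties within 1e-8 rms resolve to the smaller `|beta|`.

The parameter triple is only weakly identifiable — different optimizers
reach visually identical curves with different triples — so fit quality is
always judged in *curve space*: `compare_fits()` reports the maximum
relative transmission difference over a thickness grid, and the test suite
requires refits of noiseless model samples to reproduce transmission at the
five value layers to 1e-6, never to recover the generating triple.

`generate_synthetic_curve()` produces test fixtures: exact model values
under mean-one multiplicative lognormal noise with a chosen coefficient of
variation (`sigma² = log(1 + cv²)`), seeded and reproducible. The 2% CV
used in the recovery tests is representative of the statistical scatter of
well-converged simulated transmission data; repeated-run coefficients of
variation near 8–10% are typical of harder scatter tallies.

## Monte Carlo model

The simulator reproduces a desk-scale version of the slab geometry used to
generate broad-beam transmission data:

* a 3 m × 2 m × 2 m air-filled world; photons leaving it disappear;
* a point source emitting isotropically into the 2π hemisphere facing the
  barrier, with energies drawn from the nuclide's dominant lines (each
  photon carries the total line yield per decay as weight; F-18's 194%
  yield represents the two annihilation photons);
* a barrier of the chosen material and thickness 1 m from the source,
  spanning the full cross-section (infinite-barrier variant);
* a 2 m × 2 m × 50 cm muscle block whose central plane lies 1 m behind the
  barrier; dose is scored in 5 mm × 2.5 mm × 2.5 mm voxels, averaged over
  the second and third depth planes (≈1 cm depth, the regulatory
  deep-dose-equivalent depth) of a 150 mm diameter ROI on the beam axis;
* transmission = ROI dose with barrier / ROI dose without, from paired
  runs with per-run seeds derived from one master seed. A zero-thickness
  barrier is the no-barrier geometry, so its transmission is exactly 1.

The ceiling-floor variant shrinks the barrier to 2.14 m × 2.14 m, adds a
7.5 cm light-weight-concrete floor (tissue block resting on it, source 1 m
above) and a ceiling of the same material at 3.05/3.66/4.27/4.88 m, and
can score the ROI on the top face of the block — the configuration used to
study over-barrier scatter when the barrier itself is nearly opaque.

### Physics and its simplifications

Transport is analog: free paths from the local total attenuation
coefficient; interaction type chosen between photoelectric absorption
(full local deposition) and incoherent scattering (free-electron
Klein–Nishina sampling; energy transferred to the electron deposits
locally — the kerma approximation, no electron transport). Histories end
below 15 keV (residual deposited locally) or on leaving the world.
Deliberate simplifications, acceptable for 100–700 keV photons scored in
5 mm voxels, all documented here rather than hidden:

* **Coherent (Rayleigh) scattering omitted.** It removes little energy and
  redirects photons by small angles; its main observable effect is that
  the package's narrow-beam `mu` is a few percent smaller than reference
  total attenuation coefficients for high-Z materials.
* **No characteristic x-rays or bremsstrahlung** from the barrier
  (affects sub-1% transmissions).
* **Kerma approximation** — secondary electrons are not tracked.
* **Line spectra only** — just the dominant published lines are embedded;
  `sim_config(lines = ...)` accepts fuller user-supplied line lists.

The per-element cross-section grids (15–700 keV, log-log interpolated,
with refinement points at the Pb/Zr/Mo absorption edges) are synthetic
fixture data generated by `data-raw/make_xsec.py`: photoelectric
coefficients derived from Cromer–Liberman anomalous scattering factors,
incoherent coefficients from the free-electron Klein–Nishina cross
section. Spot checks against standard references agree to a few percent
for the photoelectric part; the incoherent part neglects binding
(exact at these energies for low Z, slightly high below ~50 keV for Pb
where photoelectric dominates anyway).

Because the transport, the sampled physics and the `mu_linear()` tables
all derive from the same embedded grids, the narrow-beam mode is an exact
self-consistency oracle: a pencil beam's unscattered survival through `x`
of material must match `exp(-mu x)` within counting statistics, whatever
the absolute accuracy of the grids.

### Statistics and problem sizes

All runs are seeded and bit-reproducible; per-history scored energies give
the relative standard deviation of each dose, which scales as `1/sqrt(N)`.
The test suite sizes each Monte Carlo check from the estimator's variance
rather than using one global history count (the scored ROI subtends only
~8×10⁻⁴ of the emission hemisphere, so deep-attenuation points need far
more histories than shoulder points):

* narrow-beam oracle checks: 2×10⁵ histories per point (binomial
  statistics, 3-sigma bands);
* broad-beam transmission curves for fitting and monotonicity: 10⁶–2×10⁶
  histories per thickness;
* buildup-versus-thickness for Tc-99m through lead: lead at 140 keV is
  photoelectric-dominated (scatter fraction ≈ 5%), so the true buildup
  exceeds 1 by only a few percent at one HVL and by tens of percent near
  the thousandth-value layer — smaller than the pointwise statistical
  error of deep-attenuation estimates at any desk-scale history count.
  `buildup_curve()` therefore shares RNG streams across thicknesses
  (common random numbers, which samples the unscattered component
  identically in every run), the probed span (0.5–1.5 mm) stays where the
  estimator variance is smaller than the expected rise, and the increase
  of B with thickness is assessed as a least-squares trend at 10⁸
  histories per run, not as pointwise ordering of noisy estimates;
* ceiling-height trend: 8×10⁶ histories per height behind an effectively
  opaque (30 mm lead) barrier, scoring the top-face ROI; the decrease of
  scatter dose with rising ceiling is likewise assessed as a log-linear
  trend plus a significant lowest-to-highest drop, because adjacent
  heights differ by as little as a few percent.

These sizes are the package's desk-scale study conditions; they trade the
figure-level precision of production runs (10⁹ histories on a cluster) for
property-level checks with explicit statistical tolerances.

## Numerical choices and edge cases

* Forward/inverse Archer evaluation switches to log-sum forms when
  `alpha*gamma*x` or `-gamma*ln T` exceeds safe exponent ranges.
* `value_layer_table()` skips unavailable pairs by default so the full
  grid reproduces the published 21-row layout; `strict = TRUE` turns a
  missing pair into an error.
* Occupancy keys match case-insensitively against the recommended-areas
  table, exact phrase (plural-insensitive) first, unique substring second;
  ambiguity is an error, not a guess.
* The kernel's RNG is xoshiro256** seeded via splitmix64; paired
  barrier/no-barrier runs use distinct streams derived from the master
  seed by a fixed affine map, so they are independent yet reproducible.
* Monte Carlo transmission estimates can exceed 1 by chance at small
  thickness; `run_curve()` caps them at 1 (and drops zero-dose points with
  a warning) so its output is always a valid curve for fitting.

## Known limitations

* The Archer parameters are treated as the definitive published set; they
  are not re-derivable bit-exactly from the desk-scale simulator, and the
  simulator's absolute transmission curves differ from the published ones
  at the few-percent level (coherent scattering omitted, line spectra
  truncated).
* In this geometry's dose-ratio transmission, the buildup factor for
  Tc-99m through *lead* stays within a few percent of 1 and its trend
  with thickness is below desk-scale statistical resolution: the
  barrier-scatter gain is nearly canceled by the extra oblique-path
  attenuation of the wide-angle tissue-scatter dose that the no-barrier
  reference includes. Compton-dominated barriers (concrete, gypsum) show
  the canonical strong buildup growth, which the test suite resolves at
  high significance.
* The solver handles one barrier between one source and one point of
  concern; room layouts with multiple sources or walls are out of scope.
* Patient self-attenuation is intentionally not modelled (sources are
  points in air), matching the convention that makes post-installation
  surveys directly comparable to the design calculation.
* The product rule for composite barriers ignores spectral hardening
  between layers; its error is demonstrated in the tests (tens of percent
  at large optical depths).
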