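# nmshield

Shielding design calculations for nuclear medicine rooms housing patients
or sources of **Tc-99m, F-18, I-131 and Lu-177** — including high-volume
Lu-177 DOTATATE and Lu-177 PSMA theranostic therapy suites, where weekly
activity-time products of thousands of mCi·h can make barrier shielding
necessary despite lutetium's low exposure-rate constant.

Photons leaving a patient are uncollimated, so a barrier is evaluated in
*broad-beam* geometry: scattered photons reach the point of concern and the
transmission exceeds the narrow-beam exponential `exp(-μx)` by the buildup
factor `B ≥ 1`. The package represents broad-beam transmission with the
three-parameter **Archer model**,

```
T(x) = [ (1 + β/α) e^{αγx} − β/α ]^{−1/γ}
```

with thickness `x` in mm, which inverts in closed form for the required
barrier thickness:

```
x = 1/(αγ) · ln[ (T^{−γ} + β/α) / (1 + β/α) ]
```

Fitted `(α, β, γ)` triples for the four radionuclides through lead, gypsum,
light/normal-weight concrete, A514 steel and glass are shipped with the
package, together with the radionuclide physical constants (half-life,
exposure-rate constant Γ, f-factor, dominant photon lines), the simulated
material compositions and recommended occupancy factors.

What the package does:

* **Barrier solver** — the standard design chain `W → D = WΓf/d² →
  T = P/(O·D) → x` from weekly workload, distance, dose limit and
  occupancy (`solve_barrier()`, `unshielded_weekly_dose()`,
  `required_transmission()`).
* **Value layers** — half/quarter/tenth/hundredth/thousandth-value layers
  from the inverse Archer equation (`value_layers()`,
  `value_layer_table()`).
* **Curve fitting** — nonlinear least-squares fitting of the Archer form to
  measured or simulated transmission curves, judged in curve space because
  the parameter triple itself is only weakly identifiable (`fit_archer()`,
  `generate_synthetic_curve()`, `compare_fits()`).
* **Monte Carlo** — a simplified analog photon transport simulator in the
  source–barrier–tissue slab geometry (point source, 2π emission toward the
  barrier, dose scored at 1 cm depth in a 150 mm ROI of a muscle block)
  that generates broad-beam transmission and buildup factors, with a
  narrow-beam mode as the analytic `exp(-μx)` oracle and a ceiling/floor
  variant for over-barrier scatter studies (`simulate_transmission()`,
  `run_curve()`, `buildup_factor()`).
* **CLI** — `inst/cli/nmshield` with verbs `solve`, `dose`, `transmission`,
  `vlayers`, `fit`, `simulate`, `dump-tables`.

## Worked example

A temporarily repurposed waiting room hosts five Lu-177 DOTATATE patients a
week (200 mCi each, 4 h residence). The adjacent office's nearest desk sits
2.40 m from the patient. Shield to the US public limit of 20 µGy/week:

```r
library(nmshield)
w  <- decay_corrected_workload(activity_mCi = 200, hours_per_session = 4,
                               sessions_per_week = 5, nuclide = "Lu-177")
sc <- shielding_scenario("Lu-177", w, "lead", distance_cm = 240,
                         limit_uGy_per_week = 20, occupancy = "office")
solve_barrier(sc)
```

```
nmshield 1.0.0 barrier solution (...)
  nuclide:                 Lu-177
  workload W:              4000 mCi h/week  [5 sessions/week x 200 mCi x 4 h]
  gamma constant:          0.181 R cm2/(mCi h) at 1 cm
  f-factor:                0.957 cGy/R
  distance d:              240 cm
  unshielded dose D:       120.3 uGy/week
  occupancy O:             1
  weekly limit P:          20 uGy/week
  required transmission T: 0.166
  barrier material:        lead
  required thickness x:    1.48 mm
```

Reading the chain: the 4000 mCi·h/week workload produces an unshielded
120.3 µGy/week at the desk; meeting 20 µGy/week at full occupancy requires
transmitting no more than 0.166 of it, which 1.48 mm of lead achieves. When
the required transmission falls below 0.01 the solver warns that scatter
over the barrier (off ceiling and floor) dominates and a single thicker
wall stops helping.

Value layers for the same pair:

```r
value_layers(get_archer_params("Lu-177", "lead"))
#>   HVL   QVL   TVL   CVL   MVL
#> 0.511 1.100 1.990 4.910 8.760   (mm)
```

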