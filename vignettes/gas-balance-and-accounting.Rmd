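---
title: "Headspace gas balance and fermentation accounting: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Headspace gas balance and fermentation accounting: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermgas)
```

`fermgas` quantifies biological H₂ and CO₂ production in nitrogen-sparged
batch bioreactors and derives the standard accounting quantities of
dark-fermentation studies. This vignette is the package's account of the
underlying science: the models, their assumptions, the parameters that
matter, and the choices made where the design was genuinely open.

## 1. The headspace mass balance

The bioreactor headspace is treated as a single well-mixed, isobaric and
isothermal gas compartment of dry volume $V = V_{HR} - V_{Steam}$. Three
gases pass through it: the N₂ carrier injected through a sparger, and the
biological H₂ and CO₂ leaving the culture. Each inlet stream is pure, so
for species $X$ with outlet fraction $p_X$ (percent of total pressure):

$$\frac{dp_X}{dt} = \frac{Q_X \cdot 100 - Q_T\, p_X}{V_{HR}-V_{Steam}},
\qquad Q_T = Q_{N_2}+Q_{CO_2}+Q_{H_2},$$

with $p_{N_2}+p_{H_2}+p_{CO_2}=100\,\%$ preserved exactly by the dynamics.
The characteristic mixing time is the residence time $V/Q_T$ (roughly
7–50 min under typical operating flows), which sets both the sampling
requirement for the forward simulation and the transient length after rate
changes.

Assumptions worth making explicit:

* **Isobaric, isothermal**: pressure dynamics and temperature excursions
  are not modelled; all volumetric flows are expressed at the headspace
  temperature, and meter readings at the reference temperature are scaled
  by $(273+T_{head})/(273+T_{ref})$.
* **Fixed vapour volume**: the water-vapour fraction of the headspace is a
  constant 320 mL. A live Antoine evaluation
  (`steam_volume_antoine()`) gives ≈ 286 mL at 69 °C with standard water
  constants; the fixed constant is retained as the operative value of the
  measurement chain being modelled, and the diagnostic documents the
  discrepancy rather than resolving it. The induced bias on reconstructed
  flows scales with the derivative term only, so it is small at
  quasi-steady operation.
* **Total flow definition**: the outlet throughput is the sum of the three
  species flows. (In the source material the CO₂ term appears once with
  its subscript dropped; it is treated as Q_CO₂.)

### Key parameters (`headspace_config()`)

| parameter | default | units | meaning |
|---|---|---|---|
| `V_HR` | 960 | mL | headspace volume |
| `V_Steam` | 320 | mL | vapour volume (fixed, see above) |
| `T_head` / `T_ref` / `T_liquid` | 69 / 20 / 80 | °C | headspace, flow-meter reference, culture |
| `P_total` | 1 | bar | total pressure |
| `h2_setpoint` | 5 | % | outlet H₂ regulation target |
| `empty_trigger_flow` | 15 | mL min⁻¹ | carrier flow ending a cycle |
| `initial_n2_flow` | 10 | mL min⁻¹ | starting carrier flow, controller floor |
| `liquid_volume` | 1.5 | L | working volume for per-litre totals |

## 2. Setpoint control of the outlet hydrogen fraction

The plant regulates the carrier flow so that outlet H₂ holds at 5 %,
keeping the dissolved H₂ low enough not to inhibit growth while keeping
the signal measurable. The control law is not documented beyond its
effect, so the package uses the *steady-state feedforward* law

$$Q_{N_2} = Q_{H_2}\frac{100-s}{s} - Q_{CO_2},$$

floored at the initial carrier flow, applied through a first-order
actuator with a 5-min time constant. This reproduces the observed
behaviour (outlet H₂ pinned at the setpoint once production exceeds the
floor) without inventing feedback gains; under a slowly varying biological
load the closed-loop simulation holds the outlet within about ±0.1
percentage points of the setpoint, comfortably inside the ±0.5 band the
package tests assert. A demand below 15 mL min⁻¹ raises the
reactor-emptying flag, which is how batch cycles end; the feeding and
emptying steps themselves are outside scope and appear only as run
boundaries.

## 3. Inverse reconstruction of biological production

Measured are the outlet fractions and the carrier flow record. Inverting
the nitrogen balance gives the total throughput
$Q_T = (100\,Q_{N_2} - V\,\dot p_{N_2})/p_{N_2}$, after which the H₂ and
CO₂ balances yield $Q_X = (V\,\dot p_X + Q_T\,p_X)/100$. Numerical
choices:

* **Derivatives** are central finite differences on the (possibly
  non-uniform) sample grid, one-sided at the ends. At the 2-min analyser
  cadence this is the highest-order estimate that does not smooth across
  genuine transients.
* **Quasi-steady-state drop**: derivative terms with
  $|\dot p| V / Q_T$ below `min_deriv_frac` (default 0.001 percentage
  points) are set to zero. The default removes only numerically
  negligible terms — keeping round-trip errors of true transients below
  1 % — while the argument allows raising the threshold towards 0.1 on
  noisy, coarsely sampled records where the derivative term is mostly
  noise amplification.
* **Negative flows** arising from measurement noise are clipped to zero
  *after* inversion and *before* integration, so cumulative production is
  non-decreasing; the unclipped values are kept in `Q_H2_raw`/`Q_CO2_raw`
  for diagnostics.
* **Molar conversion** uses the ideal gas law at headspace temperature
  and total pressure; cumulative totals are trapezoidal integrals divided
  by the working liquid volume.
* **Degenerate inputs**: a vanishing outlet N₂ fraction makes the
  inversion singular and is refused, as are non-monotone time grids and
  fraction records that fail the sum-to-100 closure beyond tolerance.

The forward and inverse paths are validated against each other: simulated
outlet records from piecewise-constant rate profiles are reconstructed to
within 1 % outside one residence time of each discontinuity, and the
closed-loop synthetic runs reconstruct cumulative H₂ within 0.1 % of the
generator's truth channel.

## 4. Dissolved CO₂

Cumulative gas-phase CO₂ misses the carbonate inventory held in the
liquid. At culture pH and headspace pCO₂ the three species follow the
equilibrium chain [CO₂]aq = K₀·pCO₂, [HCO₃⁻] = K₁[CO₂]aq/[H⁺],
[CO₃²⁻] = K₂[HCO₃⁻]/[H⁺] with [H⁺] = 10^(−pH) and constants for 80 °C
(K₀ = 0.0127 mol L⁻¹ bar⁻¹, K₁ = 4.93·10⁻⁷, K₂ = 8.18·10⁻¹¹ mol L⁻¹).
The concentrations are read as molar; no activity or ionic-strength
corrections are applied despite the saline medium, and no temperature
interpolation is attempted — the constants are overridable instead.
Whether the inventory should be added continuously or only at run end is
not dictated by the measurement chain; both modes are provided
(`total_co2_production()`), with end-of-run as the default since the
inventory is small relative to cumulative production except early in a
run.

## 5. Accounting conventions

* **Carbon recovery** compares product carbon to consumed-glucose carbon:
  C¹ counts produced cells (50 % carbon by dry weight), lactate, acetate
  and CO₂; C² adds alanine and EPS (glucose equivalents). Where CO₂ was
  not measured (serum bottles), 1 CO₂ per acetate is used
  (`co2_mode = "acetate_stoichiometric"`). Cells enter as biomass *above*
  the window-start value, so the inoculum is never counted as product.
* **Windows**: serum-bottle style rates run from inoculation to a sample
  time; bioreactor growth-phase rates run from growth onset t1 to growth
  end t2. Both are expressed through one window argument.
* **Specific rates** divide volumetric rates by the logarithmic-mean
  biomass $(X_2-X_1)/\ln(X_2/X_1)$. The convention in the source tables
  is stated only loosely ("taking into account the linear increase of
  cell concentration"); the log-mean is adopted because (i) it is the
  exact average for exponential growth at constant specific rate — for
  $X = X_0 e^{\mu t}$ and product flux $qX$, $\Delta P\,\mu/\Delta X
  = q$ identically — and (ii) it reproduces the printed specific rates
  (13.4, 18.5, 40.4 mmol g⁻¹ h⁻¹), which the arithmetic mean does not.
  The package asserts both properties.
* **Yield on thiosulfate** is an ordinary least-squares fit of maximum
  (growth-end) cell concentration on initial thiosulfate, restricted to
  the growth-limited range (≤ 0.06 mmol L⁻¹ by default): above it the
  ceiling is set by other factors and the points leave the line. The
  leftward x-intercept of the fit measures the thiosulfate-equivalent of
  the sulfur already present in the medium's yeast extract (≈ 0.03–0.04
  mmol L⁻¹ per g L⁻¹). On the four packaged table points the slope is
  3732 ± 313 mg mmol⁻¹, inside the published 3617 ± 176 band; the
  published fit presumably used replicate-level data that the printed
  means cannot recover exactly.
* **Sulfur budget**: supplied sulfur is 0.07 mmol per g of yeast extract
  (its cystine + methionine content) plus 2 S per thiosulfate; cellular
  sulfur comes from the elemental formula C₁H₁.₆O₀.₆N₀.₂S₀.₀₀₅ with a
  formula-unit mass of ≈ 26.18 g computed from standard atomic masses.
  Using integer masses shifts ratios by < 1 %, which the comparison
  tolerances absorb. One published cell-sulfur entry (0.025 mmol L⁻¹ for
  128 mg L⁻¹ of cells) recomputes to 0.0244 with this formula mass; the
  derived incorporation ratio still rounds to the published 35 %.

### Comparing recomputed values with printed tables

The packaged fixtures are printed means of triplicate cultures, rounded
to 2–4 significant figures. Derived columns recomputed from them can
therefore land a little off the printed derived values (ratio-of-means
versus mean-of-ratios, input rounding): e.g. an H₂/acetate of 9.3/5.4 =
1.72 against a printed 1.71, or a carbon recovery of 96.5 % against a
printed 96.2 %. The regression tests use a tolerance of half a unit in
the last printed digit plus 2 % of the value, and skip the cells/glucose
column for the two runs where replicate-level averaging visibly
dominates.

## 6. The synthetic generator

`simulate_run()` generates batch runs with the statistical and
stoichiometric structure the analysis assumes:

* **Growth** is logistic toward the sulfur-set ceiling
  $X_{max} = X_0 + Y_{X/Thio}\,(S_2O_3 + 0.03\,YE)$, with
  $\mu_{max} = 0.35\ h^{-1}$. A full dual-substrate Monod model is
  deliberately out of scope; the logistic form reproduces the two features
  the analysis depends on — a sulfur-proportional biomass ceiling and a
  growth phase that completes within the run, as the study's phase
  durations (10-fold biomass rise in 15–19 h with deceleration) imply.
* **Catabolism** routes consumed glucose into pathway fractions:
  acetate (glucose → 2 acetate + 2 CO₂ + 4 H₂), lactate (→ 2 lactate),
  alanine (→ 2 alanine), EPS (→ 1 glucose equivalent) and cells (≈ 144 g
  per routed mol at 50 % cell carbon). Defaults (f_ac 0.50, f_lac 0.22,
  f_ala 0.045, f_eps 0.07, cells 9 g mol⁻¹) give the observed product
  spectrum of roughly 1 acetate : 0.45 lactate : 2 H₂ : 1 CO₂ per
  glucose with ~80–90 % C² recovery. Below 0.06 mmol L⁻¹ thiosulfate,
  carbon shifts from acetate to EPS (up to 0.18 of glucose flux),
  emulating the sulfur-stress response. A small maintenance term
  (5·10⁻⁴ mmol glucose mg⁻¹ h⁻¹) continues consumption after growth.
* **Ideal mode** closes the carbon balance exactly (no maintenance, no
  side branches, acetate absorbing all non-cell carbon) and serves as the
  conservation oracle: C¹ recovery is 100 % and H₂/acetate is exactly 2.
* **Gas phase**: the H₂/CO₂ fluxes are converted to volumetric flows and
  vented through the simulated headspace under the closed-loop 5 %
  controller, producing a measured off-gas record for the inverse problem.
* **Noise** is multiplicative Gaussian (default CV 5 %), truncated at
  zero, applied to the measured channels only; noisy glucose is made
  non-decreasing by a running maximum, and noisy outlet fractions are
  renormalised to close at 100 %. The seed is part of the configuration
  and the output is bit-reproducible.

What the generator does **not** emulate: pH/NaOH titration dynamics,
growth inhibition at high H₂ partial pressure (the study operates below
the ~200 mbar critical range by design), sulfide chemistry, replicate
structure, or instrument-specific error shapes. Passing tests on
synthetic runs therefore demonstrate correctness of the computational
chain under the stated model, not robustness to every artefact of real
records.

## 7. Numerical choices and problem sizes

Integration uses `deSolve::ode` (lsoda) at relative tolerance 10⁻⁸;
closure of the simulated fractions holds to ~10⁻¹³. Time is hours at
every interface and minutes internally for flows. The test suite runs
forward/inverse round trips on 12-h records sampled at 0.5 min,
closed-loop synthetic runs of 25–30 h at the 2-min analyser cadence, a
30-seed noise study for estimator bias and a 20-sweep (4 levels each)
parameter-recovery study for Y_X/Thio — sizes chosen so the full suite
completes in well under a minute while leaving transients and noise
effects resolvable.

## 8. Known limitations

* The inverse step assumes the carrier-flow record is aligned with the
  analyser record; clock skew is not modelled or corrected.
* Uncertainties printed alongside table values are not propagated; all
  comparisons are point comparisons with explicit tolerances.
* The carbonate module ignores ionic strength (saline medium) and liquid
  out-gassing kinetics (equilibrium assumed).
* The controller model is feedforward; a plant with a detuned PID could
  show transient setpoint excursions the model does not produce.
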