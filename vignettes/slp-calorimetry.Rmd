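---
title: "Calorimetric SLP estimation in a non-adiabatic, radiating regime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calorimetric SLP estimation in a non-adiabatic, radiating regime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpfit)
```

## The physical model

A suspension of magnetic nanoparticles (mass of magnetic material $m_{np}$,
total heat capacity $C_{susp} = \sum_j m_j c_j$) sits in a cylindrical
holder, open at the top, surrounded by air at constant temperature $T_{air}$.
An alternating magnetic field does irreversible work on the particles at the
rate $SLP \cdot m_{np}$ (W). The process is isochoric (no mechanical work),
so the First Law reduces the evolution of the suspension temperature $T$ to a
power balance between the magnetic source and two loss channels:

$$
C_{susp}\,\frac{dT}{dt} \;=\; SLP\,m_{np}\,\mathbb{1}_{\text{field on}}
\;-\; \epsilon\,(T - T_{air})
\;-\; \sigma\,\eta\,A_t\,(T^4 - T_{air}^4).
$$

The linear term lumps conduction through the holder wall and convection into
the surrounding air into a single **effective thermal conductance**
$\epsilon$ (W/K); the quartic term is the net Stefan–Boltzmann radiative
exchange through the total contact area $A_t$ with emissivity $\eta$
($\sigma = 5.67\times10^{-8}$ W m$^{-2}$ K$^{-4}$, a module constant).
Temperatures are strictly absolute (Kelvin) internally — the quartic term
demands it — with Celsius accepted at file input and converted on ingestion.

Assumptions worth keeping in view:

* the environment is a heat reservoir ($dT_{air}/dt = 0$);
* the suspension is spatially uniform (lumped, no internal gradients);
* SLP is temperature-independent over the run (known to fail far above the
  biological window; the package does not model a $SLP(T)$);
* the holder wall equilibrates with the sample ($T \approx T_{ext}$), valid
  when the wall conductance dwarfs the air conductances (verified below).

### The conductance network

$\epsilon$ is a genuine physical quantity, not a fit-only parameter. With
the wall-conduction conductance of a cylindrical cup (Fourier's law solved
in the log-radial direction for the side and as a plane wall of thickness
$L$ for the bottom)

$$
\epsilon_{sh} = \kappa_{sh}\left[\frac{A_{side}}{R_{ext}\ln(R_{ext}/R_{int})}
 + \frac{A_{bottom}}{L}\right],
\qquad
\epsilon_{air,surf} = h_{air} A_{sh,ext},
\qquad
\epsilon_{air,top} = h_{air} A_{top},
$$

the electrical analogy (resistances $1/\epsilon$; wall and outer-air in
series, the open-top path in parallel) gives

$$
\epsilon = \frac{\epsilon_{sh}\,\epsilon_{air,surf}}
 {\epsilon_{sh}+\epsilon_{air,surf}} + \epsilon_{air,top}
\;\xrightarrow{\ \epsilon_{sh} \gg \epsilon_{air}\ }\;
h_{air}\,(A_{sh,ext}+A_{top}) = h_{air} A_t .
$$

For an acrylic holder ($\kappa_{sh} = 0.2$ W/(m K)) in still air
($h_{air} \approx 8$ W/(m$^2$ K)) the wall conducts an order of magnitude
better than the air convects, so the simplified form is accurate to a few
percent; `conductance_set()` always reports both. Inverting the simplified
form, a fitted $\epsilon$ yields $h_{air} = \epsilon/A_t$ — a useful sanity
check, since free-convection coefficients for gases are tabulated
(roughly 2–25 W/(m$^2$ K)). A recurring unit slip in the hyperthermia
literature writes $\epsilon$ in W/g; dimensional analysis of
$P_c = \epsilon (T - T_{air})$ fixes the unit as W/K and this package uses
W/K throughout.

The outer-wall temperature $T_{ext}$ appears only as an intermediate of the
series combination and is eliminated analytically; it is never a state
variable. Geometry can be supplied either as explicit areas or as cylinder
dimensions plus a fill height, from which areas are derived as cylinder
surfaces ($A_{side} = 2\pi R_{int} h_{fill}$,
$A_{bottom} = A_{top} = \pi R_{int}^2$); explicit areas win when both are
given. For the derived outer area we use
$A_{sh,ext} = 2\pi R_{ext} h_{fill} + \pi R_{ext}^2$ (wetted-height lateral
wall plus outer bottom): with a partially filled holder only the wall up to
the fill line carries appreciable flux, so extending the outer area to the
full cup height would overcount the escape surface.

### Closed forms and limits

With radiation switched off ($\eta = 0$) the balance is linear and the
heating solution under $T(0)=T_{air}$ is the Box–Lucas curve

$$
T(t) = T_{air} + \frac{m_{np}\,SLP}{\epsilon}
\left(1 - e^{-\epsilon t / C_{susp}}\right),
$$

with cooling the mirror-image exponential decay. Its first-order Taylor
expansion is the adiabatic ramp $T_{air} + (SLP\,m_{np}/C_{susp})\,t$ — the
basis of the classical initial-slope method, and the reason that method only
holds for $t \ll C_{susp}/\epsilon$ (about 320 s here, hence a 30 s window
stays within ~5% of linearity). At the other extreme, $dT/dt = 0$ defines
the steady state, where `slp_isothermal()` reads SLP directly off the
plateau temperature.

## Estimators

* **`slp_quasi_adiabatic()`** — OLS slope over the first `window_s` (default
  30 s, overridable) of the heating phase, scaled by $C_{susp}/m_{np}$. No
  conductance estimate. On lossy data this systematically underestimates
  SLP, by roughly $\epsilon\,w/(2C_{susp})$ relative for window $w$.
* **`fit_box_lucas()`** — Levenberg–Marquardt least squares of the Box–Lucas
  curve in $(SLP, \epsilon)$, heating segment only. Starting values: SLP
  from the initial slope; $\epsilon$ from $8\,\mathrm{W/(m^2K)} \times A_t$
  when the geometry is known, otherwise from the asymptote estimate
  $m_{np}SLP_0/(T_{end}-T_{air})$.
* **`fit_radiating()`** — the same least-squares machinery, but every
  residual evaluation integrates the full radiating ODE with RK4;
  $(SLP, \epsilon)$ free, everything else ($\sigma$, $\eta$, $A_t$,
  $T_{air}$, $C_{susp}$, $m_{np}$) held at its known value. Started from the
  Box–Lucas estimates.

Design choices that were genuinely open:

* **Optimizer.** `minpack.lm::nls.lm` with lower bounds
  $SLP \ge 0,\ \epsilon \ge 0$, `ftol = 1e-10`, `ptol = 1e-8`. Parameter
  covariance and standard errors come from
  $\hat\sigma^2 (J^\top J)^{-1}$ with a central-difference Jacobian at the
  optimum; a parametric-scatter test keeps these honest to within 50%.
* **Initial condition.** $T(0) = T_{air}$ is enforced (it is the stated
  condition of the closed form); `free_t0 = TRUE` frees it as a third
  parameter for traces that start off-ambient. Off by default.
* **Weighting.** Residuals are unweighted: a single infrared thermometer
  with temperature-independent precision is homoscedastic to a good
  approximation.
* **Background drift.** Apparatus self-heating (~1 K per 1200 s on a blank)
  can be removed with `drift_k_per_s`, subtracting a measured linear drift
  before fitting. Off by default — it requires a blank measurement, and
  applying it blindly would bias clean data.
* **Cooling.** `predict_cooling()` integrates the *fitted* model with
  $SLP = 0$ from the temperature at switch-off and reports the RMS
  discrepancy against the observed cooling — an out-of-sample check of
  $\epsilon$ (and, through the maximum temperature reached, of SLP). When a
  trace contains several off segments only the first switch-off is used.

## Numerical choices

* **Integrator.** Classic fixed-step 4th-order Runge–Kutta with internal
  substeps never exceeding `h_max` (default 0.1 s — resolves the ~320 s
  thermal timescale by more than three decades). An output interval
  straddling the field switch-off is split there, so the source
  discontinuity always lands on a step boundary. A convergence test verifies
  the global error contracts ~16× when the step halves, and an independent
  adaptive solver (deSolve's `lsoda`) agrees to better than $10^{-6}$ K.
  Non-finite states abort with the time reached.
* **Steady state.** The loss terms are strictly increasing in $T$, so the
  stationary point is the unique root of the balance above ambient. It is
  bracketed on $[T_{air},\, T_{air} + 2 m_{np} SLP/\epsilon]$ (the upper end
  overshoots the loss-free asymptote) and bisected to $10^{-10}$ K.
* **Degenerate inputs.** $\epsilon = 0$ has no Box–Lucas form (the curve
  degenerates to the adiabatic ramp) and is a structured error; the fit
  keeps $\epsilon$ off zero with a tiny lower bound and warns if it pins
  there. `expm1` keeps the saturating curve accurate for
  $\epsilon t \ll C_{susp}$. Traces must be strictly increasing in time with
  positive finite temperatures, and the field schedule must be on-then-off.

## The synthetic generator

`simulate_trace()` produces the study conditions every estimator is
validated under: the radiating ODE integrated over 600 s field-on plus
600 s field-off at 1 Hz, for a suspension of 0.1 g nanoparticles in 0.6 g
water ($C_{susp} = 2.5786$ J/K), $\eta = 0.9$, $A_t = 9.10\times10^{-4}$
m$^2$, ambient 298 K (a stated room-temperature default, not an inferred
value), then a measurement model: additive i.i.d. Gaussian noise (default
sd 0.1 K) and rounding to a 0.1 K readout resolution, mimicking a handheld
infrared thermometer, plus an optional linear drift knob for apparatus
self-heating. One integer seed drives a private RNG stream per trace
(restored afterwards), so identical seeds give byte-identical CSVs;
replicate studies derive child seeds as seed + replicate index.
`benchmark_scenarios()` packages five ground-truth $(SLP, \epsilon)$ pairs
spanning the published operating range for magnetite and magnesium-ferrite
ferrofluids (0.714–1.925 W/g, 0.00453–0.00923 W/K).

What the generator deliberately does **not** emulate: convective stirring
transients inside the suspension, temperature-dependent SLP or $h_{air}$,
ambient excursions, and non-Gaussian thermometer artifacts. Passing the
recovery suite therefore demonstrates estimator correctness *under the
model's own assumptions* plus realistic noise — it does not certify
performance on traces that violate them.

Validation problem sizes: the recovery study runs 50 traces (the five
benchmark truths × 10 seeds, 600+600 s at 1 Hz, 0.1 K noise) and requires
median parameter errors below 2% with ≥95% convergence; the ordering checks
(initial-slope underestimates; Box–Lucas $\epsilon$ exceeds the radiating
$\epsilon$ on the same trace) are asserted on every converged fit.

## Files and configuration

Traces are plain CSV (`time_s,temperature_K[,field_on]`, `temperature_C`
auto-converted; a missing schedule column can be replaced by a `t_off`
switch time). Fit results round-trip through versioned JSON
(`schema_version: "1"`, `NaN` as `null`). Configuration files are YAML or
JSON with `suspension`, `holder`, `environment` and `scenario` sections and
units encoded in key names (`r_int_m`, `kappa_sh_w_per_mk`, `t_air_k`, ...);
unknown sections are rejected. The `slpfit` executable wires the four
subcommands (`conductance`, `simulate`, `fit`, `report`) over these formats;
logs go to stderr, results to files/stdout.

## Known limitations

* The radiating fit assumes $\eta$ and $A_t$ are known; errors in either
  propagate directly into $\epsilon$ (they multiply the same quartic term).
* The lumped wall model breaks down when $\epsilon_{sh}$ is only ~10× the
  air conductances; the full network quantifies the few-percent gap but the
  ODE itself still assumes $T \approx T_{ext}$.
* Steady-state (isothermal) SLP reading requires reaching the plateau, which
  for aqueous samples happens at temperatures where the constant-SLP
  hypothesis and apparatus stability both degrade; it is provided as a
  consistency check, not a recommended primary estimator.

```{r example, eval = FALSE}
sc <- scenario_spec(slp = 1.161, eps_eff = 0.00806, seed = 1)
tr <- simulate_trace(sc)
compare_models(tr, c_susp = 2.5786, m_np = 0.1, t_air = 298)
```
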