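# slpfit

Estimation of the **specific loss power** (SLP, also called SAR) of magnetic
nanoparticle suspensions from calorimetric time–temperature traces, treating
the experiment as what it physically is: a **non-adiabatic, radiating**
system.

## The problem

In a magnetic hyperthermia experiment a ferrofluid sits in a small cylindrical
holder inside a coil; an alternating magnetic field deposits power
`SLP · m_np` (W) into the suspension, whose temperature `T(t)` is recorded —
typically ~600 s with the field on, then ~600 s of free cooling. The sample
is *not* insulated: heat leaks by conduction through the holder wall, by air
convection at the outer wall and the open top, and by thermal radiation.
`slpfit` models the full power balance of the suspension (heat capacity
`C_susp`, nanoparticle mass `m_np`, ambient temperature `T_air`):

```
C_susp dT/dt = SLP·m_np − ε·(T − T_air) − σ η A_t·(T⁴ − T_air⁴)
```

where `ε` (W/K) is the **effective thermal conductance** into the
surroundings, `σ` the Stefan–Boltzmann constant, `η` the surface emissivity
and `A_t` the sample/air contact area. `ε` is not a fudge factor: it is the
series/parallel combination of three physical conductances,

```
ε = ε_sh·ε_air,surf / (ε_sh + ε_air,surf) + ε_air,top ≈ h_air · A_t ,
```

holder-wall conduction (`ε_sh`, from the cylindrical Fourier solution), and
air convection at the outer surface and the top interface (`h_air` times each
area). The package computes this network from the holder geometry, and
conversely derives `h_air = ε/A_t` from a fitted `ε`.

Three estimators of SLP (and `ε`) are provided, in increasing physical
fidelity:

| model | assumption | estimate |
|---|---|---|
| `adiabatic` | no losses; initial 30 s linear slope | `SLP = C_susp·b/m_np` |
| `boxlucas` | linear losses only | fit of `T = T_air + (m_np·SLP/ε)(1−e^{−εt/C_susp})` |
| `radiating` | linear + radiative losses | least squares with an RK4 solution of the ODE inside the objective |

On lossy data the initial-slope method underestimates SLP, and the Box–Lucas
fit absorbs the radiative channel into an inflated `ε`; the radiating fit
corrects both. A fit can be corroborated against the cooling phase it never
saw (`SLP = 0` prediction from switch-off).

## Worked example

Simulate a trace with known ground truth (SLP = 1.925 W/g, ε = 0.00783 W/K —
a realistic magnetite suspension: 0.1 g nanoparticles in 0.6 g water,
`C_susp` = 2.5786 J/K, η = 0.9, `A_t` = 9.10·10⁻⁴ m², 0.1 K thermometer
noise), then run all three estimators:

```r
library(slpfit)
sc <- scenario_spec(slp = 1.925, eps_eff = 0.00783, seed = 42)
trace <- simulate_trace(sc)
compare_models(trace, c_susp = 2.5786, m_np = 0.1, t_air = 298)
#>       model   slp   slp_se     eps    eps_se  h_air h_air_se    rss converged
#> 1 adiabatic 1.697 0.064088      NA        NA     NA       NA 0.4443      TRUE
#> 2  boxlucas 1.938 0.003211 0.01316 3.214e-05 14.463  0.03532 6.6053      TRUE
#> 3 radiating 1.922 0.003186 0.00781 3.194e-05  8.582  0.03510 6.5468      TRUE
```

The pattern is the expected one: the initial-slope method underestimates
(1.70 vs 1.925 W/g, with a 20× larger standard error); the Box–Lucas fit
nearly recovers SLP but overestimates `ε` (0.0132 vs 0.00783 W/K) because
radiation is forced through the linear term; the radiating fit recovers both
parameters within their standard errors, and its `ε` converts to
`h_air ≈ 8.6 W/(m² K)` — free-convection territory, as it should be.
Corroborate against the cooling phase:

```r
fit <- fit_radiating(trace, c_susp = 2.5786, m_np = 0.1, t_air = 298)
predict_cooling(fit, trace)
#> Cooling prediction (radiating model): RMS discrepancy 0.114 K over 601 samples
```

— at the 0.1 K noise floor, i.e. the heating-phase parameters predict the
cooling the fit never used.

The conductance network from geometry:

```r
geom <- holder_geometry(r_int = 5.0e-3, r_ext = 6.0e-3, wall_thickness = 1.0e-3,
                        kappa_sh = 0.2, a_side = 2.40e-4, a_bottom = 7.85e-5,
                        a_sh_ext = 6.0e-4, a_top = 3.0e-4)
conductance_set(geom, environment_spec(t_air = 298, h_air = 8))
#> Thermal conductances (W/K)
#>   holder wall   eps_sh       = 0.05958
#>   outer surface eps_air,surf = 0.0048
#>   top interface eps_air,top  = 0.0024
#>   effective (full network)   = 0.006842
#>   effective (h_air * A_t)    = 0.0072
```

The wall conducts an order of magnitude better than the air moves heat away,
which is why the simplified form `ε ≈ h_air·A_t` is a good approximation.

## Command line

The same workflows are scriptable via the installed `exec/slpfit` launcher
(or `slp_cli()` from R): `conductance`, `simulate`, `fit` and `report`
subcommands operating on CSV traces, YAML/JSON configs and JSON fit results.
See `vignettes/slp-calorimetry.Rmd` for the model details and design choices.

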