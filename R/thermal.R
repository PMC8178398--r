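# Stefan-Boltzmann constant, W/(m^2 K^4). Module constant, not user-settable.
SIGMA_SB <- 5.67e-8

#' Suspension constituent
#'
#' One component of the suspension (carrier fluid, nanoparticles, ...).
#'
#' @param mass Mass in g (>= 0).
#' @param specific_heat Specific heat in J/(g K) (> 0).
#' @param label Text label.
#' @return A `constituent` object.
#' @export
constituent <- function(mass, specific_heat, label = "") {
  if (!is.numeric(mass) || mass < 0)
    stop("invalid input: constituent mass must be >= 0", call. = FALSE)
  if (!is.numeric(specific_heat) || specific_heat <= 0)
    stop("invalid input: specific heat must be > 0", call. = FALSE)
  structure(list(mass = mass, specific_heat = specific_heat, label = label),
            class = "constituent")
}

#' Nanoparticle suspension
#'
#' The suspension whose temperature is probed: a list of constituents plus the
#' nanoparticle mass (the magnetic material the loss power is normalised by)
#' and the surface emissivity used in the radiative loss term.
#'
#' @param constituents List of [constituent()] objects (at least one).
#' @param m_np Nanoparticle mass in g; must not exceed the total mass.
#' @param emissivity Dimensionless emissivity in (0, 1]; 0.9 is typical for
#'   water and acrylic surfaces.
#' @return A `suspension` object with derived heat capacity in `$c_susp`.
#' @examples
#' susp <- suspension(list(constituent(0.6, 4.186, "water"),
#'                         constituent(0.1, 0.670, "nanoparticles")),
#'                    m_np = 0.1)
#' susp$c_susp
#' @export
suspension <- function(constituents, m_np, emissivity = 0.9) {
  if (length(constituents) == 0)
    stop("invalid input: at least one constituent required", call. = FALSE)
  stopifnot(all(vapply(constituents, inherits, logical(1), "constituent")))
  total <- sum(vapply(constituents, `[[`, numeric(1), "mass"))
  if (m_np <= 0 || m_np > total)
    stop("invalid input: m_np must be in (0, total mass]", call. = FALSE)
  if (emissivity <= 0 || emissivity > 1)
    stop("invalid input: emissivity must be in (0, 1]", call. = FALSE)
  cs <- sum(vapply(constituents, function(k) k$mass * k$specific_heat,
                   numeric(1)))
  structure(list(constituents = constituents, m_np = m_np,
                 emissivity = emissivity, c_susp = cs),
            class = "suspension")
}

#' Heat capacity of a suspension
#'
#' Sum of mass times specific heat over all constituents, in J/K.
#'
#' @param x A [suspension()] or a list of [constituent()] objects.
#' @return Heat capacity in J/K.
#' @export
heat_capacity <- function(x) {
  if (inherits(x, "suspension")) return(x$c_susp)
  if (length(x) == 0)
    stop("invalid input: at least one constituent required", call. = FALSE)
  stopifnot(all(vapply(x, inherits, logical(1), "constituent")))
  sum(vapply(x, function(k) k$mass * k$specific_heat, numeric(1)))
}

#' Thermal parameter bundle for the power-balance model
#'
#' The complete parameter set of the radiating energy-balance model
#' \deqn{C_{susp}\frac{dT}{dt} = SLP\,m_{np} - \epsilon\,(T - T_{air})
#'   - \sigma\eta A_t\,(T^4 - T_{air}^4),}
#' i.e. magnetic heating against linear (conduction/convection) and
#' Stefan-Boltzmann radiative losses. Temperatures are absolute (K)
#' throughout; the quartic term demands it.
#'
#' @param slp Specific loss power (W per g of magnetic material), >= 0.
#' @param eps_eff Effective thermal conductance into the surroundings (W/K).
#' @param c_susp Heat capacity of the suspension (J/K).
#' @param m_np Nanoparticle mass (g).
#' @param emissivity Dimensionless emissivity in \[0, 1].
#' @param a_t Total external contact area (m^2).
#' @param t_air Ambient temperature (K), a heat reservoir.
#' @return A `thermal_params` object.
#' @export
thermal_params <- function(slp, eps_eff, c_susp, m_np,
                           emissivity = 0.9, a_t = 9.10e-4, t_air = 298) {
  if (c_susp <= 0) stop("invalid parameter: c_susp must be > 0", call. = FALSE)
  if (m_np <= 0) stop("invalid parameter: m_np must be > 0", call. = FALSE)
  if (a_t <= 0) stop("invalid parameter: a_t must be > 0", call. = FALSE)
  if (t_air <= 0) stop("invalid parameter: t_air must be > 0", call. = FALSE)
  if (slp < 0) stop("invalid parameter: slp must be >= 0", call. = FALSE)
  if (eps_eff < 0) stop("invalid parameter: eps_eff must be >= 0", call. = FALSE)
  if (emissivity < 0 || emissivity > 1)
    stop("invalid parameter: emissivity must be in [0, 1]", call. = FALSE)
  structure(list(slp = slp, eps_eff = eps_eff, c_susp = c_susp, m_np = m_np,
                 emissivity = emissivity, a_t = a_t, t_air = t_air,
                 sigma_sb = SIGMA_SB),
            class = "thermal_params")
}

#' @export
print.thermal_params <- function(x, ...) {
  cat(sprintf(
    "Thermal model: SLP = %g W/g, eps = %g W/K, C_susp = %g J/K, m_np = %g g\n",
    x$slp, x$eps_eff, x$c_susp, x$m_np))
  cat(sprintf("  emissivity = %g, A_t = %g m^2, T_air = %g K\n",
              x$emissivity, x$a_t, x$t_air))
  invisible(x)
}

#' Conductive/convective heat-loss rate
#'
#' Linear loss term `eps_eff * (T - t_air)` (W); positive when the suspension
#' is warmer than the environment.
#'
#' @param temp Suspension temperature (K).
#' @param params A [thermal_params()].
#' @return Power in W.
#' @export
convective_conduction_power <- function(temp, params) {
  stopifnot(inherits(params, "thermal_params"))
  params$eps_eff * (temp - params$t_air)
}

#' Radiative heat-loss rate
#'
#' Stefan-Boltzmann net exchange `sigma * eta * A_t * (T^4 - T_air^4)` (W).
#'
#' @inheritParams convective_conduction_power
#' @return Power in W.
#' @export
radiation_power <- function(temp, params) {
  stopifnot(inherits(params, "thermal_params"))
  params$sigma_sb * params$emissivity * params$a_t *
    (temp^4 - params$t_air^4)
}

#' Right-hand side of the radiating energy balance
#'
#' Instantaneous temperature rate of the suspension,
#' `(SLP*m_np*[field on] - P_c - P_rad) / C_susp` in K/s. With the field off
#' the magnetic source term is zero and the suspension relaxes toward
#' ambient.
#'
#' @inheritParams convective_conduction_power
#' @param field_on Logical; is the alternating magnetic field applied?
#' @return Rate in K/s.
#' @export
temperature_rate <- function(temp, params, field_on = TRUE) {
  stopifnot(inherits(params, "thermal_params"))
  p_mag <- if (isTRUE(field_on)) params$slp * params$m_np else 0
  (p_mag - convective_conduction_power(temp, params) -
      radiation_power(temp, params)) / params$c_susp
}

#' Instantaneous power budget
#'
#' First-Law bookkeeping at one instant for an isochoric process (no
#' mechanical work): the magnetic input power splits into internal-energy
#' storage and the two loss channels,
#' `p_mag = p_storage + p_c + p_rad`.
#'
#' @inheritParams temperature_rate
#' @param dTdt Temperature rate in K/s; if `NULL` it is taken from the model
#'   ([temperature_rate()]), making the budget balance by construction.
#' @return A list with entries `p_mag`, `p_storage`, `p_c`, `p_rad`,
#'   `p_loss = p_c + p_rad` (all W) and the residual `imbalance`.
#' @export
power_budget <- function(temp, params, field_on = TRUE, dTdt = NULL) {
  stopifnot(inherits(params, "thermal_params"))
  if (is.null(dTdt)) dTdt <- temperature_rate(temp, params, field_on)
  p_mag <- if (isTRUE(field_on)) params$slp * params$m_np else 0
  p_c <- convective_conduction_power(temp, params)
  p_rad <- radiation_power(temp, params)
  p_storage <- params$c_susp * dTdt
  list(p_mag = p_mag, p_storage = p_storage, p_c = p_c, p_rad = p_rad,
       p_loss = p_c + p_rad,
       imbalance = p_mag - p_storage - p_c - p_rad)
}

#' Box-Lucas heating curve
#'
#' Closed-form solution of the non-radiating balance for the heating phase
#' with initial condition `T(0) = t_air`:
#' \deqn{T(t) = T_{air} + \frac{m_{np}\,SLP}{\epsilon}
#'   \left(1 - e^{-\epsilon t / C_{susp}}\right),}
#' a monotone rise saturating at `t_air + m_np*slp/eps_eff`.
#'
#' @param t Time(s) since field-on, in s (vectorised).
#' @param params A [thermal_params()] with `eps_eff > 0`.
#' @return Temperature(s) in K.
#' @export
boxlucas_heating <- function(t, params) {
  stopifnot(inherits(params, "thermal_params"))
  if (params$eps_eff <= 0)
    stop("degenerate model: eps_eff = 0 has no Box-Lucas form; ",
         "use the adiabatic linear ramp", call. = FALSE)
  params$t_air + (params$m_np * params$slp / params$eps_eff) *
    (-expm1(-params$eps_eff * t / params$c_susp))
}

#' Box-Lucas cooling curve
#'
#' Exponential relaxation after field switch-off (Newton cooling from the
#' linear loss term): `T(t) = t_air + delta_t_max * exp(-eps_eff t / C_susp)`
#' with `t` measured from switch-off and `delta_t_max` the temperature excess
#' at that moment.
#'
#' @param t Time(s) since switch-off, in s (vectorised).
#' @param delta_t_max Temperature excess over ambient at switch-off (K), >= 0.
#' @param params A [thermal_params()].
#' @return Temperature(s) in K.
#' @export
boxlucas_cooling <- function(t, delta_t_max, params) {
  stopifnot(inherits(params, "thermal_params"))
  if (delta_t_max < 0)
    stop("invalid input: delta_t_max must be >= 0", call. = FALSE)
  params$t_air + delta_t_max * exp(-params$eps_eff * t / params$c_susp)
}

#' Steady-state temperature of the radiating balance
#'
#' The temperature at which magnetic input balances conductive/convective and
#' radiative losses (dT/dt = 0). The balance is strictly decreasing in T
#' above ambient, so the root is unique; it is bracketed on
#' `[t_air, t_air + 2*m_np*slp/eps_eff]` (the upper end overshoots the
#' loss-free Box-Lucas asymptote) and found by bisection.
#'
#' @param params A [thermal_params()] with `eps_eff > 0`.
#' @param tol Bisection tolerance in K.
#' @return Steady-state temperature (K).
#' @export
steady_state_temperature <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "thermal_params"))
  if (params$eps_eff <= 0)
    stop("invalid parameter: eps_eff must be > 0 to bracket the steady state",
         call. = FALSE)
  if (params$slp == 0) return(params$t_air)
  lo <- params$t_air
  hi <- params$t_air + 2 * params$m_np * params$slp / params$eps_eff
  f <- function(T) temperature_rate(T, params, field_on = TRUE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' SLP from the isothermal steady state
#'
#' Inverts the steady-state balance: given the plateau temperature `t_max`,
#' \deqn{SLP = \frac{A_t}{m_{np}}\left[h_{air}(T_{max}-T_{air})
#'   + \sigma\eta(T_{max}^4 - T_{air}^4)\right]}
#' with `h_air = eps_eff / A_t`.
#'
#' @param t_max Steady-state temperature (K); must be >= `t_air`.
#' @param params A [thermal_params()].
#' @return SLP in W/g.
#' @export
slp_isothermal <- function(t_max, params) {
  stopifnot(inherits(params, "thermal_params"))
  if (t_max < params$t_air)
    stop("invalid input: t_max must be >= t_air", call. = FALSE)
  h_air <- params$eps_eff / params$a_t
  (params$a_t / params$m_np) *
    (h_air * (t_max - params$t_air) +
       params$sigma_sb * params$emissivity * (t_max^4 - params$t_air^4))
}

# Fixed-step classic RK4 over one constant-field stretch. Scalar state;
# the RHS is inlined for speed (called hundreds of thousands of times
# inside fitting objectives).
rk4_segment <- function(T0, t0, t1, params, field_on, h_max) {
  p_mag <- if (isTRUE(field_on)) params$slp * params$m_np else 0
  eps <- params$eps_eff
  rad <- params$sigma_sb * params$emissivity * params$a_t
  ta <- params$t_air
  ta4 <- ta^4
  cs <- params$c_susp

  dt <- t1 - t0
  n <- max(1L, ceiling(dt / h_max))
  h <- dt / n
  Tn <- T0
  for (i in seq_len(n)) {
    k1 <- (p_mag - eps * (Tn - ta) - rad * (Tn^4 - ta4)) / cs
    T2 <- Tn + h / 2 * k1
    k2 <- (p_mag - eps * (T2 - ta) - rad * (T2^4 - ta4)) / cs
    T3 <- Tn + h / 2 * k2
    k3 <- (p_mag - eps * (T3 - ta) - rad * (T3^4 - ta4)) / cs
    T4 <- Tn + h * k3
    k4 <- (p_mag - eps * (T4 - ta) - rad * (T4^4 - ta4)) / cs
    Tn <- Tn + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(Tn))
      stop(sprintf("integration failure: non-finite temperature at t = %g s",
                   t0 + i * h), call. = FALSE)
  }
  Tn
}

#' Integrate the radiating energy balance
#'
#' Classic fixed-step fourth-order Runge-Kutta solution of the temperature
#' ODE, reported on an arbitrary output grid. Internal substeps never exceed
#' `h_max`; an interval straddling the field switch-off time is split there
#' so the source-term discontinuity falls on a step boundary.
#'
#' @param params A [thermal_params()].
#' @param t0_temp Initial temperature (K) at `t_grid[1]`.
#' @param t_grid Strictly increasing output times (s).
#' @param t_off Field switch-off time (s); the field is on for `t < t_off`.
#'   Use `Inf` for always-on and `-Inf` (or any value before the grid) for
#'   always-off.
#' @param h_max Maximum internal step (s); default 0.1.
#' @return A [temperature_trace()] over `t_grid`.
#' @examples
#' par <- thermal_params(slp = 1.5, eps_eff = 0.008, c_susp = 2.5786,
#'                       m_np = 0.1)
#' tr <- integrate_temperature(par, 298, seq(0, 1200), t_off = 600)
#' max(tr$temperature_K)
#' @export
integrate_temperature <- function(params, t0_temp, t_grid, t_off = Inf,
                                  h_max = 0.1) {
  stopifnot(inherits(params, "thermal_params"))
  if (length(t_grid) < 1 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (h_max <= 0) stop("h_max must be > 0", call. = FALSE)

  temps <- numeric(length(t_grid))
  temps[1] <- t0_temp
  Tn <- t0_temp
  for (j in seq_len(length(t_grid) - 1L)) {
    a <- t_grid[j]; b <- t_grid[j + 1L]
    if (a < t_off && b > t_off) {
      Tn <- rk4_segment(Tn, a, t_off, params, TRUE, h_max)
      Tn <- rk4_segment(Tn, t_off, b, params, FALSE, h_max)
    } else {
      Tn <- rk4_segment(Tn, a, b, params, a < t_off, h_max)
    }
    temps[j + 1L] <- Tn
  }
  temperature_trace(t_grid, temps, field_on = t_grid < t_off)
}
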