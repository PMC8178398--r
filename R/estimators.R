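new_slp_fit <- function(model, slp, slp_se, eps = NA_real_, eps_se = NA_real_,
                        h_air = NA_real_, h_air_se = NA_real_,
                        rss, n_points, converged, covariance = NULL,
                        t_air = NA_real_, c_susp = NA_real_, m_np = NA_real_,
                        emissivity = NA_real_, a_t = NA_real_) {
  structure(list(model = model,
                 slp = slp, slp_se = slp_se,
                 eps = eps, eps_se = eps_se,
                 h_air = h_air, h_air_se = h_air_se,
                 rss = rss, n_points = n_points, converged = converged,
                 covariance = covariance,
                 t_air = t_air, c_susp = c_susp, m_np = m_np,
                 emissivity = emissivity, a_t = a_t,
                 schema_version = "1"),
            class = "slp_fit")
}

#' @export
print.slp_fit <- function(x, ...) {
  cat(sprintf("SLP fit (%s model), %d points%s\n", x$model, x$n_points,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  SLP   = %.4g +/- %.2g W/g\n", x$slp, x$slp_se))
  if (is.finite(x$eps))
    cat(sprintf("  eps   = %.4g +/- %.2g W/K\n", x$eps, x$eps_se))
  if (is.finite(x$h_air))
    cat(sprintf("  h_air = %.4g +/- %.2g W/(m^2 K)\n", x$h_air, x$h_air_se))
  cat(sprintf("  RSS   = %.4g K^2\n", x$rss))
  invisible(x)
}

# Optional linear background drift removal (apparatus self-heating measured
# on a blank): subtracts drift * t before estimation.
apply_drift_correction <- function(trace, drift_k_per_s) {
  if (drift_k_per_s == 0) return(trace)
  out <- temperature_trace(trace$time_s,
                           trace$temperature_K - drift_k_per_s * trace$time_s,
                           trace$field_on)
  out
}

resolve_t_air <- function(trace, t_air) {
  if (!is.null(t_air)) return(t_air)
  trace$temperature_K[1]
}

#' Quasi-adiabatic (initial-slope) SLP estimate
#'
#' Ordinary least-squares slope of temperature against time over the first
#' `window_s` seconds of the heating phase, scaled to power per gram of
#' magnetic material: `SLP = C_susp * b / m_np`. Valid only while losses to
#' the environment are negligible; on real (lossy) traces it underestimates
#' the true loss power.
#'
#' @param trace A [temperature_trace()] starting at field-on.
#' @param c_susp Suspension heat capacity (J/K).
#' @param m_np Nanoparticle mass (g).
#' @param window_s Fitting window (s), default 30.
#' @param drift_k_per_s Optional linear background drift to subtract (K/s).
#' @return An object of class `slp_fit` with `model = "adiabatic"` (no
#'   conductance estimate — the method assumes no losses).
#' @export
slp_quasi_adiabatic <- function(trace, c_susp, m_np, window_s = 30,
                                drift_k_per_s = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  trace <- apply_drift_correction(trace, drift_k_per_s)
  heat <- heating_segment(trace)
  t0 <- heat$time_s[1]
  if (heat$time_s[nrow(heat)] - t0 < window_s)
    warning("window clipped: field-on segment shorter than window_s")
  sel <- heat$time_s - t0 <= window_s
  if (sum(sel) < 3)
    stop("insufficient data: need >= 3 samples in the window", call. = FALSE)
  d <- heat[sel, , drop = FALSE]
  fit <- stats::lm(temperature_K ~ time_s, data = d)
  b <- stats::coef(fit)[["time_s"]]
  b_se <- summary(fit)$coefficients["time_s", "Std. Error"]
  scale <- c_susp / m_np
  new_slp_fit(model = "adiabatic",
              slp = scale * b, slp_se = scale * b_se,
              rss = sum(stats::residuals(fit)^2), n_points = nrow(d),
              converged = TRUE,
              t_air = trace$temperature_K[1], c_susp = c_susp, m_np = m_np)
}

# Finite-difference Jacobian of a residual function at the optimum, for the
# parameter covariance sigma^2 (J'J)^-1.
fd_jacobian <- function(resid_fn, par, rel_h = 1e-6) {
  r0 <- resid_fn(par)
  J <- matrix(0, length(r0), length(par))
  for (k in seq_along(par)) {
    h <- max(abs(par[k]) * rel_h, 1e-12)
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    J[, k] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }
  J
}

ls_uncertainty <- function(resid_fn, par) {
  r <- resid_fn(par)
  n <- length(r); p <- length(par)
  rss <- sum(r^2)
  J <- fd_jacobian(resid_fn, par)
  cov <- tryCatch({
    sigma2 <- rss / max(n - p, 1)
    sigma2 * solve(crossprod(J))
  }, error = function(e) matrix(NA_real_, p, p))
  list(rss = rss, cov = cov, se = sqrt(pmax(diag(cov), 0)), n = n)
}

#' Box-Lucas (non-adiabatic, non-radiating) fit
#'
#' Nonlinear least squares of the exponential-saturation heating curve
#' `T(t) = t_air + (m_np*SLP/eps) * (1 - exp(-eps*t/C_susp))` in the two
#' parameters (SLP, eps), on the field-on segment with the initial condition
#' `T(0) = t_air` enforced. Starting values: SLP from the quasi-adiabatic
#' slope; eps from `8 W/(m^2 K) * a_t` when the contact area is known,
#' otherwise from the asymptote estimate `m_np*SLP0/(T_end - t_air)`.
#'
#' @inheritParams slp_quasi_adiabatic
#' @param t_air Ambient temperature (K); defaults to the first sample.
#' @param a_t Total external contact area (m^2), used for the eps starting
#'   value and for deriving `h_air`; may be `NULL`.
#' @param free_t0 Estimate the initial temperature as a third parameter
#'   instead of pinning it to `t_air` (off by default).
#' @return An `slp_fit` with `model = "boxlucas"`, parameter standard errors
#'   from the least-squares covariance, and `h_air = eps/a_t` when `a_t` is
#'   supplied.
#' @export
fit_box_lucas <- function(trace, c_susp, m_np, t_air = NULL, a_t = NULL,
                          free_t0 = FALSE, drift_k_per_s = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  trace <- apply_drift_correction(trace, drift_k_per_s)
  heat <- heating_segment(trace)
  t_air <- resolve_t_air(heat, t_air)
  ts <- heat$time_s - heat$time_s[1]
  Tm <- heat$temperature_K

  ad <- slp_quasi_adiabatic(trace, c_susp, m_np)
  slp0 <- max(ad$slp, 1e-6)
  eps0 <- if (!is.null(a_t)) 8 * a_t else {
    dT_end <- max(Tm[length(Tm)] - t_air, 0.1)
    m_np * slp0 / dT_end
  }

  model_T <- function(par, T0) {
    T0 + (m_np * par[1] / par[2]) * (-expm1(-par[2] * ts / c_susp))
  }
  if (free_t0) {
    resid_fn <- function(par) Tm - model_T(par, par[3])
    par0 <- c(slp = slp0, eps = eps0, t0 = t_air)
    lower <- c(0, 1e-12, 0)
  } else {
    resid_fn <- function(par) Tm - model_T(par, t_air)
    par0 <- c(slp = slp0, eps = eps0)
    lower <- c(0, 1e-12)
  }

  nl <- minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-10, ptol = 1e-8))
  par <- nl$par
  converged <- nl$info %in% 1:4
  if (!converged)
    warning(sprintf("Box-Lucas fit did not converge (info %d): %s",
                    nl$info, nl$message))
  if (par[2] <= 1e-10)
    warning("boundary: eps estimate at its lower bound")
  unc <- ls_uncertainty(resid_fn, par)
  h <- if (!is.null(a_t)) derive_h_air(par[[2]], a_t, eps_se = unc$se[2]) else
    c(h_air = NA_real_, se = NA_real_)
  new_slp_fit(model = "boxlucas",
              slp = par[[1]], slp_se = unc$se[1],
              eps = par[[2]], eps_se = unc$se[2],
              h_air = h[["h_air"]], h_air_se = h[["se"]],
              rss = unc$rss, n_points = unc$n, converged = converged,
              covariance = unc$cov[1:2, 1:2, drop = FALSE],
              t_air = t_air, c_susp = c_susp, m_np = m_np,
              emissivity = 0, a_t = if (is.null(a_t)) NA_real_ else a_t)
}

#' Non-adiabatic and radiating fit
#'
#' Nonlinear least squares of the full radiating energy balance: every
#' residual evaluation integrates the temperature ODE (fixed-step RK4) over
#' the heating phase from `T(0) = t_air`, with (SLP, eps) free and the
#' remaining quantities (`sigma`, emissivity, `a_t`, `t_air`, `C_susp`,
#' `m_np`) held at their known values. Starting values come from the
#' Box-Lucas fit.
#'
#' @inheritParams fit_box_lucas
#' @param emissivity Surface emissivity (default 0.9).
#' @param a_t Total external contact area (m^2); required (the radiative
#'   term needs it).
#' @param h_max Internal RK4 step (s).
#' @return An `slp_fit` with `model = "radiating"` and `h_air = eps/a_t`.
#' @examples
#' sc <- scenario_spec(slp = 1.161, eps_eff = 0.00806, seed = 7)
#' tr <- simulate_trace(sc)
#' fit_radiating(tr, c_susp = 2.5786, m_np = 0.1, t_air = 298)
#' @export
fit_radiating <- function(trace, c_susp, m_np, t_air = NULL,
                          emissivity = 0.9, a_t = 9.10e-4,
                          free_t0 = FALSE, drift_k_per_s = 0, h_max = 0.1) {
  stopifnot(inherits(trace, "temperature_trace"))
  trace <- apply_drift_correction(trace, drift_k_per_s)
  heat <- heating_segment(trace)
  t_air <- resolve_t_air(heat, t_air)
  ts <- heat$time_s - heat$time_s[1]
  Tm <- heat$temperature_K
  grid <- if (ts[1] > 0) c(0, ts) else ts
  keep <- if (ts[1] > 0) -1L else seq_along(grid)

  bl <- fit_box_lucas(trace, c_susp, m_np, t_air = t_air, a_t = a_t)

  model_T <- function(par, T0) {
    p <- thermal_params(slp = max(par[1], 0), eps_eff = max(par[2], 0),
                        c_susp = c_susp, m_np = m_np,
                        emissivity = emissivity, a_t = a_t, t_air = t_air)
    integrate_temperature(p, T0, grid, t_off = Inf,
                          h_max = h_max)$temperature_K[keep]
  }
  if (free_t0) {
    resid_fn <- function(par) Tm - model_T(par, par[3])
    par0 <- c(slp = bl$slp, eps = bl$eps, t0 = t_air)
    lower <- c(0, 1e-12, 0)
  } else {
    resid_fn <- function(par) Tm - model_T(par, t_air)
    par0 <- c(slp = bl$slp, eps = bl$eps)
    lower <- c(0, 1e-12)
  }

  nl <- minpack.lm::nls.lm(par = par0, lower = lower, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 100, ftol = 1e-10, ptol = 1e-8))
  par <- nl$par
  converged <- nl$info %in% 1:4
  if (!converged)
    warning(sprintf("radiating fit did not converge (info %d): %s",
                    nl$info, nl$message))
  unc <- ls_uncertainty(resid_fn, par)
  h <- derive_h_air(par[[2]], a_t, eps_se = unc$se[2])
  new_slp_fit(model = "radiating",
              slp = par[[1]], slp_se = unc$se[1],
              eps = par[[2]], eps_se = unc$se[2],
              h_air = h[["h_air"]], h_air_se = h[["se"]],
              rss = unc$rss, n_points = unc$n, converged = converged,
              covariance = unc$cov[1:2, 1:2, drop = FALSE],
              t_air = t_air, c_susp = c_susp, m_np = m_np,
              emissivity = emissivity, a_t = a_t)
}

#' Cooling-phase corroboration of a fit
#'
#' Predicts the field-off relaxation implied by a heating-phase fit — the
#' fitted model integrated with `SLP = 0` from the temperature at switch-off
#' — and reports the root-mean-square discrepancy against the observed
#' cooling samples. A fit whose loss parameters are right should predict the
#' cooling it never saw to within the measurement noise.
#'
#' @param fit An `slp_fit` from [fit_box_lucas()] or [fit_radiating()].
#' @param trace The full [temperature_trace()] including the cooling phase.
#' @param t0_temp Temperature at switch-off (K); defaults to the last
#'   field-on observation.
#' @param h_max Internal RK4 step (s), for the radiating model.
#' @return A list of class `cooling_prediction`: `trace` (predicted
#'   temperatures over the observed cooling grid) and `rmsd` (K).
#' @export
predict_cooling <- function(fit, trace, t0_temp = NULL, h_max = 0.1) {
  stopifnot(inherits(fit, "slp_fit"), inherits(trace, "temperature_trace"))
  if (!isTRUE(fit$converged))
    stop("fit did not converge; cooling prediction not meaningful",
         call. = FALSE)
  if (fit$model == "adiabatic")
    stop("the adiabatic model has no loss parameters to predict cooling",
         call. = FALSE)
  cool <- cooling_segment(trace)
  heat <- heating_segment(trace)
  if (is.null(t0_temp)) t0_temp <- heat$temperature_K[nrow(heat)]
  tc <- cool$time_s - cool$time_s[1]
  pred <- if (fit$model == "boxlucas") {
    p <- thermal_params(slp = 0, eps_eff = fit$eps, c_susp = fit$c_susp,
                        m_np = fit$m_np, emissivity = 0,
                        a_t = if (is.finite(fit$a_t)) fit$a_t else 1,
                        t_air = fit$t_air)
    boxlucas_cooling(tc, t0_temp - fit$t_air, p)
  } else {
    p <- thermal_params(slp = 0, eps_eff = fit$eps, c_susp = fit$c_susp,
                        m_np = fit$m_np, emissivity = fit$emissivity,
                        a_t = fit$a_t, t_air = fit$t_air)
    integrate_temperature(p, t0_temp, if (tc[1] > 0) c(0, tc) else tc,
                          t_off = -Inf, h_max = h_max)$temperature_K |>
      (\(x) if (tc[1] > 0) x[-1] else x)()
  }
  rmsd <- sqrt(mean((pred - cool$temperature_K)^2))
  structure(list(trace = temperature_trace(cool$time_s, pred,
                                           field_on = rep(FALSE, length(pred))),
                 rmsd = rmsd, model = fit$model),
            class = "cooling_prediction")
}

#' @export
print.cooling_prediction <- function(x, ...) {
  cat(sprintf("Cooling prediction (%s model): RMS discrepancy %.3g K over %d samples\n",
              x$model, x$rmsd, nrow(x$trace)))
  invisible(x)
}

#' Side-by-side comparison of the three estimators
#'
#' Runs the quasi-adiabatic, Box-Lucas and radiating estimators on one trace
#' and tabulates SLP, effective conductance and derived air heat-transfer
#' coefficient with their standard errors — one summary row per model.
#' Individual estimator failures are reported in the `error` column without
#' aborting the others.
#'
#' @inheritParams fit_radiating
#' @param window_s Quasi-adiabatic window (s).
#' @return A data frame of class `model_comparison` with one row per model.
#' @export
compare_models <- function(trace, c_susp, m_np, t_air = NULL,
                           emissivity = 0.9, a_t = 9.10e-4, window_s = 30,
                           drift_k_per_s = 0, h_max = 0.1) {
  stopifnot(inherits(trace, "temperature_trace"))
  runs <- list(
    adiabatic = function() slp_quasi_adiabatic(trace, c_susp, m_np, window_s,
                                               drift_k_per_s),
    boxlucas = function() fit_box_lucas(trace, c_susp, m_np, t_air, a_t,
                                        drift_k_per_s = drift_k_per_s),
    radiating = function() fit_radiating(trace, c_susp, m_np, t_air,
                                         emissivity, a_t,
                                         drift_k_per_s = drift_k_per_s,
                                         h_max = h_max))
  rows <- lapply(names(runs), function(m) {
    res <- tryCatch(runs[[m]](), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(model = m, slp = NA_real_, slp_se = NA_real_,
                 eps = NA_real_, eps_se = NA_real_,
                 h_air = NA_real_, h_air_se = NA_real_,
                 rss = NA_real_, converged = FALSE,
                 error = conditionMessage(res))
    } else {
      data.frame(model = m, slp = res$slp, slp_se = res$slp_se,
                 eps = res$eps, eps_se = res$eps_se,
                 h_air = res$h_air, h_air_se = res$h_air_se,
                 rss = res$rss, converged = res$converged, error = "")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_comparison", "data.frame")
  out
}
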