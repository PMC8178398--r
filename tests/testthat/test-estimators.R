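test_that("quasi-adiabatic slope recovers an exact linear ramp", {
  tg <- seq(0, 120, by = 1)
  tr <- temperature_trace(tg, 298 + 0.05 * tg, t_off = Inf)
  # lm warns about the noiseless perfect fit; the estimate is still exact
  fit <- suppressWarnings(slp_quasi_adiabatic(tr, c_susp = 2.5, m_np = 0.1))
  expect_equal(fit$slp, 2.5 * 0.05 / 0.1, tolerance = 1e-12)
  expect_equal(fit$model, "adiabatic")
  expect_lt(fit$slp_se, 1e-10)
  flat <- temperature_trace(tg, rep(298, length(tg)), t_off = Inf)
  expect_equal(suppressWarnings(slp_quasi_adiabatic(flat, 2.5, 0.1))$slp, 0,
               tolerance = 1e-12)
  expect_warning(
    try(slp_quasi_adiabatic(
      temperature_trace(0:1, c(298, 298.1), t_off = Inf), 2.5, 0.1),
      silent = TRUE),
    "window clipped")
})

test_that("quasi-adiabatic estimate on a saturating curve underestimates the truth", {
  p <- std_params(slp = 1.5, eps_eff = 0.008, emissivity = 0)
  tg <- seq(0, 600, by = 1)
  tr <- temperature_trace(tg, boxlucas_heating(tg, p), t_off = Inf)
  fit <- slp_quasi_adiabatic(tr, p$c_susp, p$m_np, window_s = 30)
  expect_lt(fit$slp, p$slp)
  # oracle: OLS slope of the closed form over the window, by the sum formulas
  tw <- 0:30
  Tw <- boxlucas_heating(tw, p)
  b <- sum((tw - mean(tw)) * (Tw - mean(Tw))) / sum((tw - mean(tw))^2)
  expect_equal(fit$slp, p$c_susp * b / p$m_np, tolerance = 1e-10)
})

test_that("Box-Lucas fit recovers noiseless generating parameters", {
  p <- std_params(slp = 1.925, eps_eff = 0.00783, emissivity = 0)
  tg <- seq(0, 600, by = 1)
  tr <- temperature_trace(tg, boxlucas_heating(tg, p), t_off = Inf)
  fit <- fit_box_lucas(tr, p$c_susp, p$m_np, t_air = p$t_air, a_t = p$a_t)
  expect_true(fit$converged)
  expect_equal(fit$slp, 1.925, tolerance = 1e-6)
  expect_equal(fit$eps, 0.00783, tolerance = 1e-6)
  expect_equal(fit$h_air, fit$eps / p$a_t, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-12)
})

test_that("Box-Lucas Monte-Carlo recovery stays within 2% at 0.1 K noise", {
  truth <- c(slp = 1.161, eps = 0.00806)
  err <- t(vapply(1:12, function(s) {
    sc <- scenario_spec(slp = truth["slp"], eps_eff = truth["eps"],
                        emissivity = 0, quantization_k = 0, t_off_s = 1,
                        seed = 100 + s)
    tr <- simulate_trace(sc)
    f <- fit_box_lucas(heating_segment(tr), 2.5786, 0.1, t_air = 298,
                       a_t = 9.10e-4)
    c(abs(f$slp - truth["slp"]) / truth["slp"],
      abs(f$eps - truth["eps"]) / truth["eps"])
  }, numeric(2)))
  expect_lt(stats::median(err[, 1]), 0.02)
  expect_lt(stats::median(err[, 2]), 0.02)
})

test_that("radiating fit is self-consistent on noiseless data", {
  p <- std_params(slp = 0.887, eps_eff = 0.00683)
  tg <- seq(0, 600, by = 1)
  clean <- integrate_temperature(p, p$t_air, tg, t_off = Inf, h_max = 0.1)
  fit <- fit_radiating(clean, p$c_susp, p$m_np, t_air = p$t_air,
                       emissivity = p$emissivity, a_t = p$a_t)
  expect_true(fit$converged)
  expect_equal(fit$slp, 0.887, tolerance = 1e-4)
  expect_equal(fit$eps, 0.00683, tolerance = 1e-4)
})

test_that("with emissivity 0 the radiating fit collapses onto Box-Lucas", {
  p <- std_params(slp = 1.5, eps_eff = 0.008, emissivity = 0)
  tg <- seq(0, 600, by = 1)
  tr <- temperature_trace(tg, boxlucas_heating(tg, p), t_off = Inf)
  bl <- fit_box_lucas(tr, p$c_susp, p$m_np, t_air = p$t_air, a_t = p$a_t)
  rad <- fit_radiating(tr, p$c_susp, p$m_np, t_air = p$t_air,
                       emissivity = 0, a_t = p$a_t)
  expect_equal(rad$slp, bl$slp, tolerance = 1e-6)
  expect_equal(rad$eps, bl$eps, tolerance = 1e-6)
})

test_that("Box-Lucas on radiating data absorbs radiation into inflated eps", {
  sc <- scenario_spec(slp = 1.693, eps_eff = 0.00923, noise_sd_k = 0,
                      quantization_k = 0, seed = 1)
  tr <- simulate_trace(sc)
  bl <- fit_box_lucas(heating_segment(tr), 2.5786, 0.1, t_air = 298,
                      a_t = 9.10e-4)
  expect_gt(bl$eps, 0.00923)
})

test_that("cooling prediction corroborates the heating-phase fit", {
  sc <- scenario_spec(slp = 1.925, eps_eff = 0.00783, seed = 5)
  tr <- simulate_trace(sc)
  fit <- fit_radiating(tr, 2.5786, 0.1, t_air = 298)
  pc <- predict_cooling(fit, tr)
  # discrepancy on data generated by (nearly) the fitted model is noise-level
  expect_lt(pc$rmsd, 2 * sc$noise_sd_k)
  # Box-Lucas prediction equals the closed-form exponential decay
  blfit <- fit_box_lucas(tr, 2.5786, 0.1, t_air = 298, a_t = 9.10e-4)
  pbl <- predict_cooling(blfit, tr)
  heat <- heating_segment(tr)
  t0 <- heat$temperature_K[nrow(heat)]
  cool <- cooling_segment(tr)
  closed <- boxlucas_cooling(cool$time_s - cool$time_s[1], t0 - 298,
                             thermal_params(0, blfit$eps, 2.5786, 0.1,
                                            emissivity = 0, t_air = 298))
  expect_equal(pbl$trace$temperature_K, closed, tolerance = 1e-12)
  expect_error(predict_cooling(fit, heat), "insufficient|cooling")
})

test_that("cooling discrepancy grows monotonically with eps perturbation", {
  sc <- scenario_spec(slp = 1.161, eps_eff = 0.00806, noise_sd_k = 0,
                      quantization_k = 0, seed = 2)
  tr <- simulate_trace(sc)
  fit <- fit_radiating(tr, 2.5786, 0.1, t_air = 298)
  rms <- vapply(c(1, 1.1, 1.2), function(fac) {
    f2 <- fit
    f2$eps <- fit$eps * fac
    predict_cooling(f2, tr)$rmsd
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("model comparison reproduces the expected estimator ordering", {
  sc <- scenario_spec(slp = 1.925, eps_eff = 0.00783, seed = 3)
  tr <- simulate_trace(sc)
  cmp <- compare_models(tr, 2.5786, 0.1, t_air = 298)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$model, c("adiabatic", "boxlucas", "radiating"))
  expect_true(all(cmp$converged))
  slp <- stats::setNames(cmp$slp, cmp$model)
  eps <- stats::setNames(cmp$eps, cmp$model)
  expect_lt(slp["adiabatic"], slp["radiating"])
  expect_lte(slp["radiating"], slp["boxlucas"] + 1e-6)
  expect_lt(eps["radiating"], eps["boxlucas"])
  # failures are reported per-model, not thrown
  degenerate <- temperature_trace(0:1, c(298, 298.05), t_off = Inf)
  cmp2 <- suppressWarnings(compare_models(degenerate, 2.5786, 0.1,
                                          t_air = 298))
  expect_equal(nrow(cmp2), 3)
  expect_true(all(!cmp2$converged))
  expect_true(all(nzchar(cmp2$error)))
})

test_that("reported standard errors match the parametric scatter within 1.5x", {
  ests <- t(vapply(1:40, function(s) {
    sc <- scenario_spec(slp = 1.161, eps_eff = 0.00806, quantization_k = 0,
                        t_off_s = 1, seed = 400 + s)
    tr <- simulate_trace(sc)
    f <- fit_radiating(heating_segment(tr), 2.5786, 0.1, t_air = 298)
    c(f$slp, f$eps, f$slp_se, f$eps_se)
  }, numeric(4)))
  ratio_slp <- stats::sd(ests[, 1]) / mean(ests[, 3])
  ratio_eps <- stats::sd(ests[, 2]) / mean(ests[, 4])
  expect_gt(ratio_slp, 1 / 1.5); expect_lt(ratio_slp, 1.5)
  expect_gt(ratio_eps, 1 / 1.5); expect_lt(ratio_eps, 1.5)
})

test_that("linear-drift subtraction removes the apparatus-heating bias", {
  drift <- 1 / 1200  # ~1 K over a 1200 s run
  sc <- scenario_spec(slp = 1.161, eps_eff = 0.00806, drift_k_per_s = drift,
                      noise_sd_k = 0, quantization_k = 0, seed = 6)
  tr <- simulate_trace(sc)
  biased <- fit_radiating(tr, 2.5786, 0.1, t_air = 298)
  corrected <- fit_radiating(tr, 2.5786, 0.1, t_air = 298,
                             drift_k_per_s = drift)
  truth <- 1.161
  expect_gt(abs(biased$slp - truth), abs(corrected$slp - truth))
  expect_lt(abs(corrected$slp - truth) / truth, 0.005)
})
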