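# Forward model: kernel, component regressors, condition simulation,
# amplitude fitting, gain estimation.

test_that("hrf kernel is causal beyond delta, peaks at delta + (n-1)*tau, unit area", {
  t <- seq(0, 60, by = 0.01)
  h_raw <- hrf_kernel(t, hrf_params(), normalize = FALSE)
  expect_true(all(h_raw[t <= 3] == 0))
  # analytic unit area of the gamma form, checked by quadrature
  expect_equal(sum(h_raw) * 0.01, 1, tolerance = 1e-3)
  h <- hrf_kernel(t, hrf_params())
  expect_equal(t[which.max(h)], 7, tolerance = 0.0101)
  expect_equal(sum(h) * 0.01, 1, tolerance = 1e-12)
  # parameter sweep: mode tracks delta + (n-1) tau
  for (p in list(hrf_params(1.5, 2, 2), hrf_params(3, 4, 0))) {
    hp <- hrf_kernel(t, p)
    expect_equal(t[which.max(hp)], p$delay_s + (p$order - 1) * p$tau_s,
                 tolerance = 0.0101)
  }
  expect_error(hrf_params(tau_s = 0), class = "oscivm_config_error")
  expect_error(hrf_params(order = 2.5), class = "oscivm_config_error")
})

test_that("component regressors have the stated shapes and impulse normalization", {
  cmp <- model_components(a_ramp = 0.27)
  regs <- component_regressors(cmp, grid_step_s = 0.01, delay_ms = 150)
  at <- function(tt) which.min(abs(regs$time - tt))
  expect_equal(regs$ramp[at(-0.55)], 0.27, tolerance = 1e-9)
  expect_true(all(regs$ramp[regs$time > -0.54] == 0))
  expect_true(all(regs$ramp[regs$time < -2.001] == 0))
  expect_equal(regs$ramp[at(-2)], 0, tolerance = 1e-9)
  expect_true(all(regs$boxcar[regs$time > -0.55 & regs$time < 4] == cmp$a_box))
  # delta integral = gain * a_vis, independent of the grid step
  for (dt in c(0.01, 0.005)) {
    r2 <- component_regressors(cmp, grid_step_s = dt, delay_ms = 150, gain = 1.33)
    expect_equal(sum(r2$delta) * dt, 1.33 * cmp$a_vis, tolerance = 1e-9)
  }
  zero <- model_components(a_ramp = 0, a_box = 0, a_vis = 0)
  rz <- component_regressors(zero)
  expect_true(all(rz$ramp == 0) && all(rz$boxcar == 0) && all(rz$delta == 0))
  expect_error(component_regressors(cmp, delay_ms = 60000),
               class = "oscivm_config_error")
  expect_error(model_components(a_box = 0.1), class = "oscivm_config_error")
})

test_that("condition curves obey linearity, M1 identity and time invariance", {
  cmp <- model_components()
  trough <- simulate_condition(cmp, condition = "va_trough", delay_ms = 150)
  peak <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150)
  vis <- simulate_condition(cmp, condition = "vision_only", delay_ms = 150)
  g <- unname(cmp$gain["peak"])
  expect_equal(peak$response - trough$response, (g - 1) * vis$response,
               tolerance = 1e-10)
  expect_equal(peak$lag_values - trough$lag_values, (g - 1) * vis$lag_values,
               tolerance = 1e-10)
  # action_only carries no delta: identical for any delay
  a1 <- simulate_condition(cmp, condition = "action_only", delay_ms = 70)
  a2 <- simulate_condition(cmp, condition = "action_only", delay_ms = 310)
  expect_identical(a1$response, a2$response)
  # shifting the delta shifts the output by the same number of samples
  v0 <- simulate_condition(cmp, condition = "vision_only", delay_ms = 0)
  v5 <- simulate_condition(cmp, condition = "vision_only", delay_ms = 500)
  k <- round(0.5 / 0.01)
  n <- length(v0$response)
  expect_equal(v5$response[(k + 1):n], v0$response[1:(n - k)], tolerance = 1e-10)
  zero <- model_components(a_ramp = 0, a_box = 0, a_vis = 0)
  expect_true(all(simulate_condition(zero, condition = "va_peak")$response == 0))
})

test_that("TR samples converge as the fine grid is refined", {
  cmp <- model_components()
  v1 <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150,
                           grid_step_s = 0.01)$lag_values
  v2 <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150,
                           grid_step_s = 0.005)$lag_values
  expect_lt(max(abs(v1 - v2)), 1e-4)
})

test_that("amplitude fitting recovers noiseless self-simulations exactly", {
  cmp <- model_components(a_ramp = 0.27, a_box = -0.2, a_vis = 10)
  obs <- simulate_condition(cmp, condition = "va_trough", delay_ms = 70)$lag_values
  fit <- fit_component_amplitudes(obs, cmp, free = c("a_ramp", "a_box", "a_vis"),
                                  delay_ms = 70)
  expect_equal(unname(fit$estimates), c(0.27, -0.2, 10), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # g free with a_vis fixed
  peak <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150)$lag_values
  fitg <- fit_component_amplitudes(peak, cmp, free = "g", delay_ms = 150)
  expect_equal(unname(fitg$estimates[["g"]]), 1.33, tolerance = 1e-6)
  expect_error(fit_component_amplitudes(obs, cmp, free = c("g", "a_vis")),
               class = "oscivm_config_error")
})

test_that("amplitude estimates are unbiased under additive noise", {
  cmp <- model_components()
  truth <- simulate_condition(cmp, condition = "va_trough", delay_ms = 70)$lag_values
  set.seed(42)
  n_rep <- 200
  est <- t(replicate(n_rep, {
    fit_component_amplitudes(truth + rnorm(7, 0, 0.05), cmp,
                             free = c("a_ramp", "a_box", "a_vis"),
                             delay_ms = 70)$estimates
  }))
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  bias <- colMeans(est) - c(0.27, -0.2, 10)
  expect_true(all(abs(bias) <= 2 * mc_se + 1e-12))
})

test_that("visual gain estimation: identity, recovery, suppression", {
  cmp <- model_components()
  trough <- simulate_condition(cmp, condition = "va_trough", delay_ms = 70)$lag_values
  expect_equal(estimate_visual_gain(trough, trough, delay_peak_ms = 70)$g, 1,
               tolerance = 1e-9)
  peak <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150)$lag_values
  est <- estimate_visual_gain(trough, peak)
  expect_equal(est$g, 1.33, tolerance = 1e-6)
  expect_equal(est$r_squared_peak, 1, tolerance = 1e-9)
  # no positivity clamp
  low <- simulate_condition(cmp, condition = "va_peak", delay_ms = 150,
                            gain = 0.8)$lag_values
  expect_lt(estimate_visual_gain(trough, low)$g, 1)
  flat <- model_components(a_ramp = 0.3, a_box = -0.1, a_vis = 0)
  act <- simulate_condition(flat, condition = "va_trough", delay_ms = 70)$lag_values
  expect_error(estimate_visual_gain(act, act), class = "oscivm_singular_error")
})
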