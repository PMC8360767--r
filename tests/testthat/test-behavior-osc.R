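# Behavioral oscillation analysis: binning, sinusoid OLS, frequency scan,
# permutation correction, subject GLM and Hotelling test.

test_that("bin_accuracy: hand-counted example, bin count, trivial cases", {
  trials <- data.frame(subject_id = "s", correct = c(1, 1, 0, 1, 1, 0),
                       delay_ms = c(5, 15, 25, 25, 35, 45))
  s <- bin_accuracy(trials, 20)
  expect_equal(s$prop_correct, c(1, 2 / 3, 0))
  expect_equal(s$n_trials, c(2L, 3L, 1L))
  expect_equal(s$bin_center_s, c(0.010, 0.030, 0.050))

  full <- data.frame(subject_id = "s", delay_ms = seq(0, 600, 10), correct = 1)
  s2 <- bin_accuracy(full, 20, delay_range_ms = c(0, 600))
  expect_equal(nrow(s2), 30L)
  expect_true(all(s2$prop_correct == 1))
  expect_equal(sum(s2$n_trials), 61L) # closed right edge keeps delay 600

  sparse <- data.frame(subject_id = "s", delay_ms = c(5, 5, 595), correct = c(1, 0, 1))
  s3 <- bin_accuracy(sparse, 20, delay_range_ms = c(0, 600))
  expect_true(is.na(s3$prop_correct[2]))
  expect_equal(s3$n_trials[2], 0L)

  expect_error(bin_accuracy(trials[0, ]), class = "oscivm_input_error")
})

test_that("sinusoid OLS: exact interpolation, constant series, rank guard", {
  s <- make_sine_series(5, amp = 0.1, baseline = 0.7)
  fit <- fit_sinusoid_at_frequency(s, 5)
  expect_equal(c(fit$beta0, fit$beta1, fit$beta2), c(0.7, 0.1, 0),
               tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  const <- make_sine_series(5, amp = 0, baseline = 0.8)
  cf <- fit_sinusoid_at_frequency(const, 7)
  expect_equal(cf$beta0, 0.8, tolerance = 1e-12)
  expect_equal(cf$amplitude, 0, tolerance = 1e-12)
  expect_equal(cf$r_squared, 0)

  # f = 50 Hz aliases the 20 ms bin grid: sin column is identically ~0
  expect_error(fit_sinusoid_at_frequency(s, 50), class = "oscivm_singular_error")
  expect_error(fit_sinusoid_at_frequency(s[1:3, ], 5), class = "oscivm_input_error")
})

test_that("OLS solution matches brute-force amplitude/phase minimization", {
  set.seed(7)
  s <- make_sine_series(5.4, amp = 0.08, baseline = 0.7)
  s$prop_correct <- s$prop_correct + rnorm(nrow(s), 0, 0.02)
  f <- 5.4
  fit <- fit_sinusoid_at_frequency(s, f)
  x <- s$bin_center_s
  y <- s$prop_correct
  amps <- seq(0, 0.5, length.out = 601)
  phases <- seq(0, 2 * pi, length.out = 629)[-629]
  best <- c(Inf, NA, NA)
  yc <- y - mean(y)
  for (ph in phases) {
    sn <- sin(2 * pi * f * x + ph)
    snc <- sn - mean(sn)
    # beta0 optimal in closed form; RSS(A) is quadratic in A
    rss <- sum(yc^2) - 2 * amps * sum(yc * snc) + amps^2 * sum(snc^2)
    i <- which.min(rss)
    if (rss[i] < best[1]) best <- c(rss[i], amps[i], ph)
  }
  expect_lt(abs(fit$amplitude - best[2]), 2 * 0.5 / 600)
  dphi <- (fit$phase_rad - best[3] + pi) %% (2 * pi) - pi
  expect_lt(abs(dphi), 2 * 2 * pi / 628 + 0.02)
})

test_that("frequency scan: grid size, tie rule, exact recovery, OLS equivalence", {
  s <- make_sine_series(5.4, amp = 0.1)
  sc <- scan_frequency_grid(s, 2, 20, 0.1)
  expect_equal(nrow(sc$spectrum), 181L)
  expect_equal(sc$best$freq_hz, 5.4)
  expect_equal(sc$best$r_squared, 1, tolerance = 1e-10)

  const <- make_sine_series(3, amp = 0)
  sc0 <- scan_frequency_grid(const)
  expect_equal(sc0$best$freq_hz, 2) # tie broken toward the lowest frequency
  expect_true(all(sc0$spectrum$r_squared == 0))

  # the projection shortcut must equal exhaustive per-frequency OLS
  set.seed(11)
  s$prop_correct <- s$prop_correct + rnorm(nrow(s), 0, 0.03)
  sc2 <- scan_frequency_grid(s, 2, 8, 0.5)
  naive <- vapply(sc2$spectrum$freq_hz, function(f) {
    fit_sinusoid_at_frequency(s, f)$r_squared
  }, numeric(1))
  expect_equal(sc2$spectrum$r_squared, naive, tolerance = 1e-12)
})

test_that("r_squared is invariant to affine rescaling of the series", {
  set.seed(3)
  s <- make_sine_series(4.2, amp = 0.06)
  s$prop_correct <- s$prop_correct + rnorm(nrow(s), 0, 0.02)
  f1 <- fit_sinusoid_at_frequency(s, 4.2)
  s2 <- s
  s2$prop_correct <- 3.5 * s$prop_correct - 1.2
  f2 <- fit_sinusoid_at_frequency(s2, 4.2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("amplitude/phase reparameterization reproduces the fit pointwise", {
  set.seed(5)
  s <- make_sine_series(6.1, amp = 0.09)
  s$prop_correct <- s$prop_correct + rnorm(nrow(s), 0, 0.02)
  fit <- fit_sinusoid_at_frequency(s, 6.1)
  x <- s$bin_center_s
  lhs <- fit$beta1 * sin(2 * pi * 6.1 * x) + fit$beta2 * cos(2 * pi * 6.1 * x)
  rhs <- fit$amplitude * sin(2 * pi * 6.1 * x + fit$phase_rad)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("permutation test: add-one rule, degenerate data, determinism", {
  cfg <- generator_config(seed = 21, n_trials = 3000, osc_amp = 0.25,
                          osc_freq_hz = 5.4, baseline_acc = 0.6)
  trials <- gen_behavior_trials(cfg)
  pr <- permutation_corrected_pvalue(trials, n_perm = 999, seed = 4)
  # strong signal: observed exceeds every surrogate maximum
  expect_equal(sum(pr$null_max_r2 >= pr$observed_best$r_squared), 0)
  expect_equal(pr$p_corrected, 1 / 1000)
  expect_true(pr$exceeds_95th)

  pr2 <- permutation_corrected_pvalue(trials, n_perm = 999, seed = 4)
  expect_identical(pr$null_max_r2, pr2$null_max_r2)
  expect_identical(pr$p_corrected, pr2$p_corrected)

  degen <- data.frame(subject_id = "s", delay_ms = seq(0, 600, 10), correct = 1)
  expect_warning(pd <- permutation_corrected_pvalue(degen, n_perm = 100),
                 "degenerate")
  expect_equal(pd$p_corrected, 1)
  expect_error(permutation_corrected_pvalue(trials, n_perm = 10),
               class = "oscivm_config_error")
})

test_that("subject sine GLM: null, constructed signal, bin-fit consistency", {
  set.seed(9)
  n <- 20000
  d <- sample(seq(0, 600, 10), n, replace = TRUE)
  null_trials <- data.frame(subject_id = "s", delay_ms = d,
                            correct = rbinom(n, 1, 0.7))
  b0 <- subject_sine_glm(null_trials, 5)
  se <- sqrt(0.21 / n) * sqrt(2) # rough OLS slope SE on orthonormal-ish sines
  expect_lt(abs(b0[["beta_sin"]]), 6 * se)
  expect_lt(abs(b0[["beta_cos"]]), 6 * se)

  # deterministic square wave at 5 Hz over exactly 3 cycles
  d2 <- seq(0, 590, 10)
  det <- data.frame(subject_id = "s", delay_ms = d2,
                    correct = as.integer(sin(2 * pi * 5 * d2 / 1000) > 0))
  b1 <- subject_sine_glm(det, 5)
  expect_gt(b1[["beta_sin"]], 0.5)
  # discrete duty-cycle asymmetry leaves a small cosine component
  expect_lt(abs(b1[["beta_cos"]]), 0.15)

  cfg <- generator_config(seed = 13, n_trials = 30000, osc_amp = 0.1,
                          osc_freq_hz = 5)
  trials <- gen_behavior_trials(cfg)
  bt <- subject_sine_glm(trials, 5)
  bf <- fit_sinusoid_at_frequency(bin_accuracy(trials, 10), 5)
  expect_equal(bt[["beta_sin"]], bf$beta1, tolerance = 0.02)
  expect_equal(bt[["beta_cos"]], bf$beta2, tolerance = 0.02)

  expect_error(subject_sine_glm(det[1:5, ], 5), class = "oscivm_input_error")
})

test_that("Hotelling T2: zero mean, independent oracle, singular guard", {
  sym <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  h0 <- hotelling_t2_test(sym)
  expect_equal(h0$t2, 0, tolerance = 1e-12)
  expect_equal(h0$p_value, 1)

  # oracle via stats::mahalanobis (independent x' S^-1 x implementation)
  pairs <- rbind(c(1, 0), c(1.2, 0.1), c(0.8, -0.1), c(1.0, 0.05))
  h <- hotelling_t2_test(pairs)
  t2_oracle <- nrow(pairs) *
    stats::mahalanobis(colMeans(pairs), c(0, 0), cov(pairs))
  expect_equal(h$t2, t2_oracle, tolerance = 1e-9)
  expect_equal(h$df, c(2, 2))

  # collinear deviations give a singular covariance
  collinear <- rbind(c(1, 0), c(1.2, 0.1), c(0.8, -0.1), c(1, 0))
  expect_error(hotelling_t2_test(collinear), class = "oscivm_singular_error")
  expect_error(hotelling_t2_test(sym[1:2, ]), class = "oscivm_input_error")
})
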