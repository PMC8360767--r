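# FIR deconvolution GLM and delay-modulation statistics.

test_that("preprocessing: constant, ramp, scale, zero-mean guard", {
  expect_equal(preprocess_roi_series(rep(5, 40)), rep(0, 34), tolerance = 1e-12)
  expect_equal(preprocess_roi_series(seq(1, 80, length.out = 40)),
               rep(0, 34), tolerance = 1e-10)
  tt <- 1:106
  raw <- 100 + sin(2 * pi * tt / 12)
  out <- preprocess_roi_series(raw)
  expect_equal((max(out) - min(out)) / 2, 1, tolerance = 0.05) # ~1 %BOLD
  expect_error(preprocess_roi_series(c(rep(1, 6), rep(0, 30))),
               class = "oscivm_input_error")
  expect_error(preprocess_roi_series(1:5), class = "oscivm_input_error")
})

test_that("events shift with preprocessing and early events are dropped", {
  ev <- data.frame(run_id = 1, onset_s = c(10, 40), duration_s = 0.033,
                   trial_type = c("d70", "d150"), delay_ms = c(70, 150),
                   event_tr = c(3L, 13L))
  expect_warning(ev2 <- adjust_events_for_preprocessing(ev, 6, 3), "removed")
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$event_tr, 7L)
  expect_equal(ev2$onset_s, 22)
})

test_that("FIR design: column structure, indexing, guards", {
  ev <- data.frame(run_id = 1, trial_type = c("d70", "d150", "d230", "d310"),
                   event_tr = c(5L, 20L, 40L, 60L))
  X <- build_fir_design(ev, 80)
  expect_equal(ncol(X), 29L) # 4 types x 7 lags + constant
  expect_equal(sum(colnames(X) != "constant"), 28L)
  expect_true(all(X[, "constant"] == 1))

  X0 <- build_fir_design(ev[0, ], 80, types = character(0))
  expect_equal(colnames(X0), "constant")

  ev1 <- data.frame(run_id = 1, trial_type = "A", event_tr = 10L)
  X1 <- build_fir_design(ev1, 30)
  expect_equal(which(X1[, "A:lag2"] == 1), 13L) # 0-based TR 12 -> row 13
  expect_equal(sum(X1[, "A:lag2"]), 1)

  late <- data.frame(run_id = 1, trial_type = "A", event_tr = 25L)
  expect_error(build_fir_design(late, 30), class = "oscivm_input_error")
  twin <- data.frame(run_id = 1, trial_type = "A", event_tr = c(5L, 5L))
  expect_warning(build_fir_design(twin, 30), "overlapping")
})

test_that("FIR GLM: white-noise nulls, R2 oracle, invariances", {
  set.seed(31)
  n_tr <- 400
  ev <- data.frame(run_id = 1,
                   trial_type = rep(c("d70", "d150"), 10),
                   event_tr = as.integer(seq(5, 385, length.out = 20)))
  bold <- data.frame(run_id = 1, tr_index = 0:(n_tr - 1), roi = "V1",
                     value = rnorm(n_tr))
  fit <- fit_fir_glm(bold, ev, "V1")
  expect_true(all(abs(fit$betas) < 3 * 1 / sqrt(10) * 3)) # |beta| << 3 SE-ish
  # independent R2 recomputation
  resid <- unlist(fit$residuals, use.names = FALSE)
  y <- bold$value
  expect_equal(fit$r_squared, 1 - sum(resid^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  # residuals orthogonal to every design column
  X <- build_fir_design(ev, n_tr, types = c("d150", "d70"))
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)

  # adding a constant moves only the constant beta
  bold2 <- bold
  bold2$value <- bold$value + 5
  fit2 <- fit_fir_glm(bold2, ev, "V1")
  expect_equal(fit2$betas, fit$betas, tolerance = 1e-10)
  expect_equal(fit2$constant, fit$constant + 5, tolerance = 1e-10)

  # collinear columns are named: duplicate events of two types at same TRs
  ev_bad <- data.frame(run_id = 1, trial_type = rep(c("A", "B"), each = 3),
                       event_tr = rep(c(10L, 60L, 110L), 2))
  err <- tryCatch(fit_fir_glm(bold, ev_bad, "V1"), error = identity)
  expect_s3_class(err, "oscivm_singular_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("response amplitude summarizes lags 1-4", {
  fit <- structure(list(betas = rbind(d70 = c(0, 1, 2, 3, 4, 0, 0),
                                      d150 = rep(0, 7)),
                        window_tr = 7L), class = "glm_fit")
  amp <- response_amplitude(fit)
  expect_equal(unname(amp["d70"]), 2.5) # (1+2+3+4)/4
  expect_equal(unname(amp["d150"]), 0)
  fit$betas["d70", ] <- c(0, 1, 4, 2, 3, 0, 0)
  expect_equal(unname(response_amplitude(fit, method = "trapezoid")["d70"]),
               (0.5 * 1 + 4 + 2 + 0.5 * 3) / 3)
  fit$window_tr <- 4L
  expect_error(response_amplitude(fit), class = "oscivm_input_error")
})

test_that("delay contrasts: Holm step-down oracle and guards", {
  set.seed(41)
  n <- 14
  base <- rnorm(n)
  amp <- cbind(d70 = base + rnorm(n, 0, 0.6),
               d150 = base + 0.5 + rnorm(n, 0, 0.6),
               d230 = base + rnorm(n, 0, 0.6),
               d310 = base + 0.4 + rnorm(n, 0, 0.6))
  res <- delay_contrasts(amp)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$df == n - 1))
  # independent Holm implementation: sorted p * (m - i + 1), monotone, capped
  m <- length(res$p)
  o <- order(res$p)
  holm <- pmin(cummax(res$p[o] * (m - seq_len(m) + 1)), 1)
  expect_equal(res$p_holm[o], holm, tolerance = 1e-12)
  expect_true(all(res$p_holm >= res$p))

  one <- delay_contrasts(amp, pairs = list(c("d150", "d70")))
  expect_equal(one$p_holm, one$p)

  same <- cbind(d70 = 1:5, d150 = 1:5 + 2)
  expect_error(delay_contrasts(cbind(same, d230 = 1:5, d310 = 2:6),
                               pairs = list(c("d150", "d70"))),
               class = "oscivm_input_error")
})

test_that("repeated-measures ANOVA: null, t2 identity, df, aov oracle", {
  m_eq <- matrix(rep(rnorm(4), 3), 4, 3) # subject offsets, equal condition values
  expect_equal(rm_anova_delays(m_eq)$f, 0, tolerance = 1e-12)

  set.seed(51)
  m2 <- cbind(a = rnorm(10), b = rnorm(10, 0.5))
  res2 <- rm_anova_delays(m2)
  tt <- t.test(m2[, 2], m2[, 1], paired = TRUE)
  expect_equal(res2$f, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)

  m4 <- matrix(rnorm(17 * 4), 17, 4)
  res4 <- rm_anova_delays(m4)
  expect_equal(res4$df, c(3, 48))
  # oracle: base aov with an Error(subject) stratum
  df_long <- data.frame(y = as.vector(m4),
                        cond = factor(rep(1:4, each = 17)),
                        subj = factor(rep(1:17, 4)))
  av <- summary(stats::aov(y ~ cond + Error(subj / cond), data = df_long))
  f_aov <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res4$f, f_aov, tolerance = 1e-9)

  m4[2, 3] <- NA
  expect_error(rm_anova_delays(m4), class = "oscivm_input_error")
})

test_that("Rayleigh test: antipodal, concentrated, calibrated", {
  r0 <- rayleigh_uniformity(c(0, pi))
  expect_equal(r0$rbar, 0, tolerance = 1e-12)
  expect_equal(r0$z, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  rc <- rayleigh_uniformity(rep(1.3, 20))
  expect_lt(rc$p, 1e-6)

  set.seed(61)
  ps <- replicate(1000, rayleigh_uniformity(runif(100, 0, 2 * pi))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(rayleigh_uniformity(numeric(0)), class = "oscivm_input_error")
})
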