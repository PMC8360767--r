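# Shared fixtures, all built in code.

# Exact sinusoidal accuracy series on the standard 20 ms bin grid.
make_sine_series <- function(freq_hz, amp = 0.1, baseline = 0.7,
                             bin_width_ms = 20, delay_max_ms = 600) {
  centers <- seq(bin_width_ms / 2, delay_max_ms - bin_width_ms / 2,
                 by = bin_width_ms) / 1000
  out <- data.frame(bin_center_s = centers,
                    prop_correct = baseline + amp * sin(2 * pi * freq_hz * centers),
                    n_trials = 100L)
  class(out) <- c("accuracy_series", "data.frame")
  out
}

# Minimal glm_fit stand-in carrying only what the connectivity stage reads.
fake_glm_fit <- function(residuals_by_run, roi = "V1") {
  structure(list(residuals = residuals_by_run,
                 runs = as.numeric(names(residuals_by_run)),
                 roi = roi),
            class = "glm_fit")
}

# Residual epochs built directly from a shared + independent noise model:
# a = z * gain + e1, b = z * gain + e2 per (event, offset) cell, with gains
# applied per delay. Returns a residual_epochs object.
make_epochs <- function(n_per_delay, delays, shared_sd = 1, noise_sd = 1,
                        gain_by_delay = NULL, seed = 1,
                        gain_offsets = seq_len(6)) {
  set.seed(seed)
  delay_ms <- rep(delays, times = n_per_delay)
  n <- length(delay_ms)
  z <- matrix(rnorm(n * 6, 0, shared_sd), n, 6)
  g <- if (is.null(gain_by_delay)) {
    rep(1, n)
  } else {
    unname(gain_by_delay[as.character(delay_ms)])
  }
  zg <- z
  zg[, gain_offsets] <- z[, gain_offsets] * g
  a <- zg + matrix(rnorm(n * 6, 0, noise_sd), n, 6)
  b <- zg + matrix(rnorm(n * 6, 0, noise_sd), n, 6)
  structure(list(delay_ms = delay_ms, a = a, b = b, offsets = -1:4,
                 n_dropped = 0L, roi_a = "V1", roi_b = "M1"),
            class = "residual_epochs")
}

# Generator config for noiseless exact-recovery worlds.
noiseless_config <- function(seed = 1, n_runs = 2, ...) {
  generator_config(seed = seed, n_runs = n_runs, noise_sd = 0,
                   shared_sd = 0, drift_slope = 0, ...)
}
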