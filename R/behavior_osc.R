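# Detection of rhythmic modulation of accuracy over visuo-motor delay.
#
# Accuracy binned over delay is fit with
#   y(x) = b0 + b1 sin(2 pi f x) + b2 cos(2 pi f x)
# at every frequency of a scan grid; significance of the best fit is assessed
# against the max-R^2 distribution of label-shuffled surrogates, which
# corrects for the frequency search automatically. Group-level phase/amplitude
# consistency uses single-trial sine/cosine regressions per subject and a
# bivariate Hotelling T-squared test.

#' Bin trial accuracy over visuo-motor delay
#'
#' Non-overlapping fixed-width bins; the bin center is left edge + width / 2,
#' converted to seconds so frequencies are in Hz. The final right edge is
#' closed so the maximum delay is not dropped. Bins with zero trials are kept
#' in the output (`prop_correct = NA`) but flagged and excluded from fitting.
#'
#' @param trials A `trial_table` with `delay_ms` and `correct`.
#' @param bin_width_ms Bin width in ms (default 20).
#' @param delay_range_ms Range covered by the bins; default `c(0, max)`
#'   rounded up to a whole number of bins.
#' @return A `data.frame` (class `accuracy_series`) with `bin_center_s`,
#'   `prop_correct`, `n_trials`.
#' @export
bin_accuracy <- function(trials, bin_width_ms = 20, delay_range_ms = NULL) {
  if (is.null(trials) || nrow(trials) == 0) abort_input("empty trial table")
  if (!all(trials$correct %in% c(0, 1))) abort_input("correct must be 0/1")
  w <- bin_width_ms
  if (is.null(delay_range_ms)) {
    delay_range_ms <- c(0, ceiling(max(trials$delay_ms) / w) * w)
  }
  lo <- delay_range_ms[1]
  n_bins <- ceiling((delay_range_ms[2] - lo) / w)
  if (n_bins < 1) abort_input("degenerate delay range")
  idx <- pmin(floor((trials$delay_ms - lo) / w), n_bins - 1L) + 1L
  if (any(idx < 1L)) abort_input("delays below the bin range")
  n <- tabulate(idx, nbins = n_bins)
  hits <- vapply(seq_len(n_bins), function(b) {
    sum(trials$correct[idx == b])
  }, numeric(1))
  out <- data.frame(bin_center_s = (lo + w * (seq_len(n_bins) - 0.5)) / 1000,
                    prop_correct = ifelse(n > 0, hits / pmax(n, 1), NA_real_),
                    n_trials = n)
  class(out) <- c("accuracy_series", "data.frame")
  out
}

#' Fit the sinusoid at one frequency
#'
#' Unweighted ordinary least squares of the binned accuracy on
#' `[1, sin(2 pi f x), cos(2 pi f x)]`, with `x` the bin centers in seconds.
#' `r_squared = 1 - SS_res / SS_tot`, defined as 0 for a constant series.
#'
#' @param series An `accuracy_series`.
#' @param freq_hz Frequency in Hz (> 0).
#' @return Object of class `sinusoid_fit` with `freq_hz`, `beta0`, `beta1`,
#'   `beta2`, `r_squared`, `amplitude` and `phase_rad`
#'   (`b1 sin + b2 cos = A sin(2 pi f x + phase)`).
#' @export
fit_sinusoid_at_frequency <- function(series, freq_hz) {
  if (!.is_number(freq_hz) || freq_hz <= 0) abort_config("freq_hz must be > 0")
  keep <- !is.na(series$prop_correct) & series$n_trials > 0
  x <- series$bin_center_s[keep]
  y <- series$prop_correct[keep]
  if (length(x) < 4) abort_input("need at least 4 non-empty bins")
  X <- cbind(1, sin(2 * pi * freq_hz * x), cos(2 * pi * freq_hz * x))
  qx <- qr(X)
  if (qx$rank < 3L) {
    abort_singular(sprintf("singular sinusoid design at %.4g Hz", freq_hz))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  structure(list(freq_hz = freq_hz, beta0 = beta[1], beta1 = beta[2],
                 beta2 = beta[3], r_squared = max(0, r2),
                 amplitude = sqrt(beta[2]^2 + beta[3]^2),
                 phase_rad = atan2(beta[3], beta[2]),
                 n_bins = length(x)),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf("<sinusoid_fit> f = %.2f Hz | R^2 = %.3f | amp = %.4f | phase = %.3f rad\n",
              x$freq_hz, x$r_squared, x$amplitude, x$phase_rad))
  invisible(x)
}

# Orthonormal (centered) sine/cosine basis per frequency, for fast projection
# R^2. Returns an n x (2 * n_freq) matrix; rank-deficient frequencies get
# zero columns and are marked in `ok`.
.freq_basis <- function(x, freqs) {
  n <- length(x)
  B <- matrix(0, n, 2L * length(freqs))
  ok <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    s <- sin(2 * pi * freqs[i] * x)
    cc <- cos(2 * pi * freqs[i] * x)
    M <- cbind(s - mean(s), cc - mean(cc))
    qm <- qr(M)
    r <- qm$rank
    if (r >= 1L) {
      Q <- qr.Q(qm)[, seq_len(r), drop = FALSE]
      B[, 2L * i - 1L + seq_len(r) - 1L] <- Q
      ok[i] <- r == 2L
    }
  }
  list(B = B, ok = ok, freqs = freqs)
}

# R^2 spectrum for each column of Y (bins x datasets) given a basis.
.spectrum_from_basis <- function(basis, Y) {
  Y <- as.matrix(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sst <- colSums(Yc^2)
  P2 <- crossprod(basis$B, Yc)^2
  nf <- length(basis$freqs)
  odd <- 2L * seq_len(nf) - 1L
  num <- P2[odd, , drop = FALSE] + P2[odd + 1L, , drop = FALSE]
  r2 <- sweep(num, 2L, pmax(sst, .Machine$double.eps), "/")
  r2[, sst <= 0] <- 0
  r2
}

#' Scan a frequency grid for the best sinusoidal fit
#'
#' Fits every frequency on the inclusive grid `seq(f_min, f_max, step)` and
#' returns the R^2 maximizer (ties broken toward the lowest frequency) plus
#' the full spectrum. The projection shortcut used internally is numerically
#' identical to per-frequency OLS.
#'
#' @param series An `accuracy_series`.
#' @param f_min,f_max,f_step Grid bounds and step in Hz (defaults 2--20 by
#'   0.1, i.e. 181 frequencies).
#' @return List with `best` (a `sinusoid_fit`) and `spectrum`
#'   (`data.frame(freq_hz, r_squared)`).
#' @export
scan_frequency_grid <- function(series, f_min = 2, f_max = 20, f_step = 0.1) {
  if (f_min >= f_max || f_step <= 0) abort_config("need f_min < f_max, step > 0")
  freqs <- f_min + f_step * (0:round((f_max - f_min) / f_step))
  keep <- !is.na(series$prop_correct) & series$n_trials > 0
  x <- series$bin_center_s[keep]
  y <- series$prop_correct[keep]
  if (length(x) < 4) abort_input("need at least 4 non-empty bins")
  basis <- .freq_basis(x, freqs)
  r2 <- as.vector(.spectrum_from_basis(basis, matrix(y, ncol = 1L)))
  if (all(!basis$ok) && all(r2 == 0)) {
    # distinguish "constant series" (legit, R^2 = 0) from all-singular designs
    if (stats::var(y) > 0) abort_singular("all frequencies singular on this bin grid")
  }
  best_i <- which.max(replace(r2, !basis$ok, -Inf)) # first max = lowest freq on ties
  best <- fit_sinusoid_at_frequency(series, freqs[best_i])
  list(best = best,
       spectrum = data.frame(freq_hz = freqs, r_squared = r2))
}

#' Permutation-corrected p value for the best sinusoidal fit
#'
#' Correct/incorrect labels are shuffled across trials (delays fixed), the
#' accuracy series re-binned and the full grid re-scanned for every surrogate;
#' the maximum R^2 per surrogate forms the null. Using all free parameters on
#' the surrogates corrects for the multiple comparisons of the frequency
#' search. p uses the add-one rule `(1 + #null >= observed) / (n_perm + 1)`;
#' the 95th-percentile exceedance criterion is reported alongside.
#'
#' @param trials A `trial_table`.
#' @param f_min,f_max,f_step Frequency grid (Hz).
#' @param bin_width_ms Bin width for the accuracy series.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the shuffles.
#' @return Object of class `perm_result` with `observed_best`, `null_max_r2`,
#'   `p_corrected`, `exceeds_95th`, `n_perm`, `seed`.
#' @export
permutation_corrected_pvalue <- function(trials, f_min = 2, f_max = 20,
                                         f_step = 0.1, bin_width_ms = 20,
                                         n_perm = 1000L, seed = 1L) {
  if (!.is_count(n_perm) || n_perm < 100) abort_config("n_perm must be >= 100")
  y <- trials$correct
  if (all(y == 1) || all(y == 0)) {
    warning("degenerate trial table (all correct or all incorrect); p = 1",
            call. = FALSE)
    return(structure(list(observed_best = NULL,
                          null_max_r2 = rep(NA_real_, n_perm),
                          p_corrected = 1, exceeds_95th = FALSE,
                          n_perm = as.integer(n_perm), seed = as.integer(seed)),
                     class = "perm_result"))
  }
  series <- bin_accuracy(trials, bin_width_ms)
  obs <- scan_frequency_grid(series, f_min, f_max, f_step)
  keep <- series$n_trials > 0
  # bin membership is fixed across permutations (delays are not shuffled)
  w <- bin_width_ms
  n_bins <- nrow(series)
  bin_idx <- pmin(floor(trials$delay_ms / w), n_bins - 1L) + 1L
  n_per_bin <- tabulate(bin_idx, nbins = n_bins)
  x <- series$bin_center_s[keep]
  freqs <- f_min + f_step * (0:round((f_max - f_min) / f_step))
  basis <- .freq_basis(x, freqs)
  set.seed(seed)
  n <- length(y)
  S <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  # rowsum returns one row per non-empty bin in ascending index order, which
  # is exactly the set of bins retained by `keep`
  sums <- rowsum(S, bin_idx)
  props <- sums / n_per_bin[n_per_bin > 0]
  null_max <- apply(.spectrum_from_basis(basis, props), 2L, max)
  p <- (1 + sum(null_max >= obs$best$r_squared)) / (n_perm + 1)
  structure(list(observed_best = obs$best, spectrum = obs$spectrum,
                 null_max_r2 = null_max, p_corrected = p,
                 exceeds_95th = obs$best$r_squared >
                   stats::quantile(null_max, 0.95, names = FALSE),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  if (is.null(x$observed_best)) {
    cat("<perm_result> degenerate data, p = 1\n")
  } else {
    cat(sprintf("<perm_result> best f = %.2f Hz, R^2 = %.3f | p_corrected = %.4g (%d perms)\n",
                x$observed_best$freq_hz, x$observed_best$r_squared,
                x$p_corrected, x$n_perm))
  }
  invisible(x)
}

#' Single-trial sine/cosine regression for one subject
#'
#' Least squares of the 0/1 outcome on `[1, sin(2 pi f d), cos(2 pi f d)]`,
#' `d` in seconds (linear probability model).
#'
#' @param trials Trials of a single subject.
#' @param freq_hz Frequency of interest in Hz.
#' @return Named numeric `c(beta_sin, beta_cos)`.
#' @export
subject_sine_glm <- function(trials, freq_hz) {
  if (nrow(trials) < 10) abort_input("need at least 10 trials per subject")
  d <- trials$delay_ms / 1000
  X <- cbind(1, sin(2 * pi * freq_hz * d), cos(2 * pi * freq_hz * d))
  qx <- qr(X)
  if (qx$rank < 3L) {
    abort_singular(sprintf("constant predictor column at %.4g Hz", freq_hz))
  }
  beta <- qr.coef(qx, trials$correct)
  c(beta_sin = unname(beta[2]), beta_cos = unname(beta[3]))
}

#' Hotelling T-squared test of (sin, cos) coefficients against zero
#'
#' `T2 = n * xbar' S^{-1} xbar` with the sample covariance `S`;
#' `F = T2 (n - 2) / (2 (n - 1))` is compared to `F(2, n - 2)`.
#'
#' @param beta_pairs An n x 2 matrix (or list of length-2 vectors) of
#'   per-subject (beta_sin, beta_cos) pairs, n >= 3.
#' @return Object of class `hotelling_result` with `t2`, `f_stat`, `df`,
#'   `p_value`, `mean`, `n`.
#' @export
hotelling_t2_test <- function(beta_pairs) {
  if (is.list(beta_pairs)) beta_pairs <- do.call(rbind, beta_pairs)
  beta_pairs <- as.matrix(beta_pairs)
  n <- nrow(beta_pairs)
  if (n < 3 || ncol(beta_pairs) != 2) {
    abort_input("need an n x 2 matrix with n >= 3 subjects")
  }
  xbar <- colMeans(beta_pairs)
  S <- stats::cov(beta_pairs)
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    abort_singular("singular covariance of beta pairs; jitter the inputs or add subjects")
  }
  t2 <- n * as.numeric(t(xbar) %*% Sinv %*% xbar)
  f_stat <- t2 * (n - 2) / (2 * (n - 1))
  p <- stats::pf(f_stat, 2, n - 2, lower.tail = FALSE)
  structure(list(per_subject_betas = beta_pairs, mean = xbar, n = n,
                 t2 = t2, f_stat = f_stat, df = c(2, n - 2), p_value = p),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("<hotelling_result> T2 = %.3f, F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$t2, x$df[1], x$df[2], x$f_stat, x$p_value, x$n))
  invisible(x)
}
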