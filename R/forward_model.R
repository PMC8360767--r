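# Forward ("toy") model of the visuo-motor BOLD response.
#
# Three neural input components on a fine time grid around action onset:
#   * a ramp (readiness potential / motor preparation) rising before the action,
#   * a negative boxcar (sustained suppression tied to the synchronized
#     oscillation) spanning action onset,
#   * a delta (the brief visual stimulus) at action onset + visuo-motor delay,
# each convolved with a gamma-family hemodynamic kernel and summed. A
# condition-specific multiplicative gain g on the delta models rhythmic
# excitability: g = 1 at trough delays and g > 1 at peak delays.

#' Hemodynamic kernel parameters
#'
#' Gamma-family impulse response with decay time `tau_s`, integer `order`
#' and pure onset delay `delay_s`. Defaults correspond to a standard early
#' visual cortex hemodynamic response peaking at `delay_s + (order-1)*tau_s`
#' = 7 s.
#'
#' @param tau_s Decay time constant in seconds (> 0).
#' @param order Gamma order (integer >= 1).
#' @param delay_s Pure onset delay in seconds (>= 0).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(tau_s = 2, order = 3, delay_s = 3) {
  if (!.is_number(tau_s) || tau_s <= 0) abort_config("tau_s must be > 0")
  if (!.is_count(order)) abort_config("order must be a positive integer")
  if (!.is_number(delay_s) || delay_s < 0) abort_config("delay_s must be >= 0")
  structure(list(tau_s = tau_s, order = as.integer(order), delay_s = delay_s),
            class = "hrf_params")
}

#' Evaluate the hemodynamic kernel on a time grid
#'
#' \eqn{h(t) = 0} for \eqn{t \le \delta}; for \eqn{t > \delta},
#' \eqn{h(t) = ((t-\delta)/\tau)^{n-1} e^{-(t-\delta)/\tau} / (\tau (n-1)!)}.
#' The analytic form integrates to 1 over \eqn{[\delta, \infty)}; with
#' `normalize = TRUE` (default) the kernel is rescaled to unit area on the
#' supplied grid, so component amplitudes keep the percent-BOLD scale of their
#' inputs. The grid should span the kernel support (roughly
#' `delay_s + 10 * tau_s`) for the normalization to be meaningful.
#'
#' @param t Non-negative, uniformly spaced time grid in seconds.
#' @param params An [hrf_params()] object.
#' @param normalize Rescale to unit area on `t` (requires >= 2 grid points).
#' @return Numeric vector of kernel values, same length as `t`.
#' @export
hrf_kernel <- function(t, params = hrf_params(), normalize = TRUE) {
  if (!inherits(params, "hrf_params")) params <- do.call(hrf_params, params)
  if (length(t) == 0L || any(!is.finite(t)) || any(t < 0)) {
    abort_config("t must be a non-negative finite grid")
  }
  tau <- params$tau_s
  n <- params$order
  del <- params$delay_s
  u <- (t - del) / tau
  h <- ifelse(t <= del, 0, u^(n - 1L) * exp(-pmax(u, 0)) / (tau * factorial(n - 1L)))
  if (normalize && length(t) >= 2L) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
      abort_config("t must be uniformly spaced when normalize = TRUE")
    }
    area <- sum(h) * dt[1]
    if (area > 0) h <- h / area
  }
  h
}

#' Neural input components of the forward model
#'
#' @param a_ramp Ramp (motor preparation) peak amplitude, percent BOLD units.
#' @param a_box Boxcar (oscillatory suppression) amplitude; must be <= 0.
#' @param a_vis Visual delta impulse integral (percent BOLD x s).
#' @param gain Named multipliers on the visual delta per condition class;
#'   must contain `trough` and `peak`, both > 0.
#' @param ramp_window,boxcar_window Start/end times in seconds relative to
#'   action onset; the ramp must precede the boxcar.
#' @param ramp_plateau If `TRUE` the ramp holds its peak after its end time
#'   instead of returning to zero (the default reads "completed by" as
#'   back-to-baseline).
#' @return An object of class `model_components`.
#' @export
model_components <- function(a_ramp = 0.27, a_box = -0.2, a_vis = 10,
                             gain = c(trough = 1, peak = 1.33),
                             ramp_window = c(-2, -0.55),
                             boxcar_window = c(-0.55, 4),
                             ramp_plateau = FALSE) {
  if (!.is_number(a_ramp) || !.is_number(a_box) || !.is_number(a_vis)) {
    abort_config("component amplitudes must be finite scalars")
  }
  if (a_box > 0) abort_config("boxcar amplitude a_box must be <= 0")
  if (!all(c("trough", "peak") %in% names(gain)) || any(gain <= 0)) {
    abort_config("gain must be a named vector with positive 'trough' and 'peak'")
  }
  if (ramp_window[1] >= ramp_window[2] || boxcar_window[1] >= boxcar_window[2]) {
    abort_config("component windows must have start < end")
  }
  if (ramp_window[2] > boxcar_window[1] + 1e-9) {
    abort_config("ramp must be completed before the boxcar starts")
  }
  structure(list(a_ramp = a_ramp, a_box = a_box, a_vis = a_vis,
                 gain = gain, ramp_window = ramp_window,
                 boxcar_window = boxcar_window, ramp_plateau = ramp_plateau),
            class = "model_components")
}

#' Fine-grid component regressors
#'
#' Builds the three neural input series on a uniform grid. The delta is a
#' unit-integral impulse: its sample value is `gain * a_vis / grid_step_s`, so
#' its time integral equals `gain * a_vis` independent of the step.
#'
#' @param components A [model_components()] object.
#' @param grid_step_s Grid step in seconds (default 0.01).
#' @param t_range Grid span in seconds relative to action onset.
#' @param delay_ms Visuo-motor delay: the delta sits at `delay_ms / 1000` s.
#' @param gain Multiplier applied to the delta amplitude.
#' @return List with `time`, `ramp`, `boxcar`, `delta`, `grid_step_s`.
#' @export
component_regressors <- function(components = model_components(),
                                 grid_step_s = 0.01, t_range = c(-5, 25),
                                 delay_ms = 0, gain = 1) {
  dt <- grid_step_s
  n <- round((t_range[2] - t_range[1]) / dt)
  t <- t_range[1] + dt * (0:n)

  eps <- 1e-9 # guards window edges against grid round-off
  rw <- components$ramp_window
  ramp <- numeric(length(t))
  in_ramp <- t >= rw[1] - eps & t <= rw[2] + eps
  ramp[in_ramp] <- components$a_ramp * (t[in_ramp] - rw[1]) / (rw[2] - rw[1])
  if (components$ramp_plateau) ramp[t > rw[2] + eps] <- components$a_ramp

  bw <- components$boxcar_window
  boxcar <- ifelse(t >= bw[1] - eps & t <= bw[2] + eps, components$a_box, 0)

  t_vis <- delay_ms / 1000
  if (t_vis < t_range[1] || t_vis > t_range[2]) {
    abort_config(sprintf("visual onset %.3f s outside grid [%g, %g]",
                         t_vis, t_range[1], t_range[2]))
  }
  delta <- numeric(length(t))
  delta[which.min(abs(t - t_vis))] <- gain * components$a_vis / dt

  list(time = t, ramp = ramp, boxcar = boxcar, delta = delta,
       grid_step_s = dt)
}

# Trapezoid edge weighting for sampled piecewise inputs with jumps at their
# support boundaries: halving the first/last nonzero sample makes the
# discrete convolution a trapezoid quadrature (O(dt^2) instead of O(dt)).
# Not applied to the delta, which is an impulse, not a sampled function.
.trapezoid_edges <- function(v) {
  nz <- which(v != 0)
  if (length(nz) >= 1L) {
    v[nz[1]] <- v[nz[1]] / 2
    v[nz[length(nz)]] <- v[nz[length(nz)]] / 2
  }
  v
}

# Causal discrete convolution of an input series with the hemodynamic kernel,
# evaluated on the same grid as the input.
.convolve_hrf <- function(x, dt, hrf) {
  h <- hrf_kernel(dt * (seq_along(x) - 1L), hrf, normalize = TRUE)
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_along(x)] * dt
}

#' Simulate the BOLD response for one condition
#'
#' Sums the condition-appropriate inputs (vision_only: delta; action_only:
#' ramp + boxcar; va_trough / va_peak: all three with the trough or peak gain
#' on the delta), convolves with the hemodynamic kernel on the fine grid, and
#' samples the result at TR lags 0..`n_lags - 1` after action onset.
#'
#' @param components A [model_components()] object.
#' @param hrf An [hrf_params()] object.
#' @param condition One of `"vision_only"`, `"action_only"`, `"va_trough"`,
#'   `"va_peak"`.
#' @param delay_ms Visuo-motor delay of the visual input in ms.
#' @param gain Optional explicit delta gain, overriding the condition default.
#' @param grid_step_s,t_range Fine grid (see [component_regressors()]).
#' @param tr_s Repetition time in seconds.
#' @param n_lags Number of TR samples (default 7, i.e. 0..18 s at TR 3 s).
#' @return An object of class `simulated_curve` with fields `time`,
#'   `response` (fine grid), `lag_times_s`, `lag_values`, `condition`,
#'   `delay_ms`, `gain`.
#' @export
simulate_condition <- function(components = model_components(),
                               hrf = hrf_params(),
                               condition = c("va_trough", "va_peak",
                                             "vision_only", "action_only"),
                               delay_ms = 0, gain = NULL,
                               grid_step_s = 0.01, t_range = c(-5, 25),
                               tr_s = 3, n_lags = 7L) {
  condition <- match.arg(condition)
  g <- gain %||% switch(condition,
                        vision_only = 1,
                        action_only = 1,
                        va_trough = unname(components$gain["trough"]),
                        va_peak = unname(components$gain["peak"]))
  regs <- component_regressors(components, grid_step_s, t_range, delay_ms, g)
  ramp_w <- .trapezoid_edges(regs$ramp)
  box_w <- .trapezoid_edges(regs$boxcar)
  input <- switch(condition,
                  vision_only = regs$delta,
                  action_only = ramp_w + box_w,
                  va_trough = ,
                  va_peak = ramp_w + box_w + regs$delta)
  y <- .convolve_hrf(input, regs$grid_step_s, hrf)
  lag_times <- tr_s * (seq_len(n_lags) - 1L)
  idx <- round((lag_times - t_range[1]) / regs$grid_step_s) + 1L
  if (any(idx < 1L | idx > length(y))) {
    abort_config("TR lag times fall outside the fine grid")
  }
  structure(list(time = regs$time, response = y,
                 lag_times_s = lag_times, lag_values = y[idx],
                 condition = condition, delay_ms = delay_ms, gain = g),
            class = "simulated_curve")
}

#' @export
print.simulated_curve <- function(x, ...) {
  cat(sprintf("<simulated_curve> %s, delay %g ms, gain %.3f\n",
              x$condition, x$delay_ms, x$gain))
  cat("  TR samples:", paste(sprintf("%.4f", x$lag_values), collapse = " "), "\n")
  invisible(x)
}

# Unit-amplitude TR-sampled basis curves for the three components.
.component_basis <- function(components, hrf, delay_ms, grid_step_s = 0.01,
                             t_range = c(-5, 25), tr_s = 3, n_lags = 7L) {
  unit <- components
  mk <- function(a_ramp, a_box, a_vis) {
    u <- unit
    u$a_ramp <- a_ramp; u$a_box <- a_box; u$a_vis <- a_vis
    u
  }
  sim <- function(cmp, cond) {
    simulate_condition(cmp, hrf, cond, delay_ms = delay_ms, gain = 1,
                       grid_step_s = grid_step_s, t_range = t_range,
                       tr_s = tr_s, n_lags = n_lags)$lag_values
  }
  list(ramp = sim(mk(1, 0, 0), "action_only"),
       # a unit boxcar basis must be positive; the sign lives in a_box
       boxcar = {
         u <- unit; u$a_ramp <- 0; u$a_vis <- 0; u$a_box <- 0
         bw <- u$boxcar_window
         regs <- component_regressors(u, grid_step_s, t_range, delay_ms, 1)
         box1 <- ifelse(regs$time >= bw[1] - 1e-9 & regs$time <= bw[2] + 1e-9,
                        1, 0)
         y <- .convolve_hrf(.trapezoid_edges(box1), grid_step_s, hrf)
         lag_times <- tr_s * (seq_len(n_lags) - 1L)
         y[round((lag_times - t_range[1]) / grid_step_s) + 1L]
       },
       vis = sim(mk(0, 0, 1), "vision_only"))
}

#' Fit component amplitudes to an observed lag curve
#'
#' Ordinary least squares of an observed TR-sampled response on the convolved
#' unit-amplitude component curves. Any subset of `a_ramp`, `a_box`, `a_vis`
#' and the visual gain `g` may be free; the remaining components enter as a
#' fixed offset. When `g` is free, `a_vis` must be fixed: `g` is then solved
#' linearly on the `a_vis`-scaled delta regressor.
#'
#' @param observed Numeric vector of TR-sampled response values (length 7 by
#'   default conventions).
#' @param components A [model_components()] object holding the fixed values.
#' @param hrf An [hrf_params()] object.
#' @param free Character subset of `c("a_ramp", "a_box", "a_vis", "g")`.
#' @param delay_ms Visuo-motor delay of the visual input in ms.
#' @param gain Fixed delta gain used for the non-free visual part (default:
#'   1 unless `g` is free).
#' @param grid_step_s,t_range,tr_s Fine-grid and sampling settings.
#' @return List with `estimates` (named), `r_squared`, `fitted`.
#' @export
fit_component_amplitudes <- function(observed, components = model_components(),
                                     hrf = hrf_params(),
                                     free = c("a_ramp", "a_box", "a_vis"),
                                     delay_ms = 0, gain = 1,
                                     grid_step_s = 0.01, t_range = c(-5, 25),
                                     tr_s = 3) {
  free <- match.arg(free, c("a_ramp", "a_box", "a_vis", "g"),
                    several.ok = TRUE)
  if ("g" %in% free && "a_vis" %in% free) {
    abort_config("g and a_vis cannot both be free (their product is what is identified)")
  }
  n_lags <- length(observed)
  if (n_lags < length(free)) {
    abort_input("need at least as many data points as free amplitudes")
  }
  basis <- .component_basis(components, hrf, delay_ms, grid_step_s, t_range,
                            tr_s, n_lags)
  reg <- list(a_ramp = basis$ramp, a_box = basis$boxcar,
              a_vis = gain * basis$vis, g = components$a_vis * basis$vis)
  # reg$a_vis already carries the fixed gain, so the fixed-part multiplier
  # for a_vis is the bare amplitude
  fixed_amp <- c(a_ramp = components$a_ramp, a_box = components$a_box,
                 a_vis = components$a_vis, g = 0)
  fixed_part <- numeric(n_lags)
  for (nm in c("a_ramp", "a_box", "a_vis")) {
    if (!(nm %in% free) && !("g" %in% free && nm == "a_vis")) {
      fixed_part <- fixed_part + fixed_amp[[nm]] * reg[[nm]]
    }
  }
  X <- do.call(cbind, reg[free])
  colnames(X) <- free
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort_singular(paste("collinear component curves at TR sampling:",
                         paste(free[-seq_len(qx$rank)], collapse = ", ")))
  }
  est <- qr.coef(qx, observed - fixed_part)
  fitted <- fixed_part + as.vector(X %*% est)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(estimates = stats::setNames(as.vector(est), free),
       r_squared = r2, fitted = fitted)
}

#' Estimate the visual gain between trough and peak responses
#'
#' Two-step procedure: (1) fit `a_ramp`, `a_box`, `a_vis` on the trough-delay
#' curve (gain fixed at 1); (2) hold those amplitudes and fit the single gain
#' multiplier `g` on the peak-delay curve. No positivity clamp: suppression
#' (g < 1) is reported as estimated.
#'
#' @param trough_curve,peak_curve TR-sampled observed lag curves, same length.
#' @param components,hrf Model settings; amplitudes in `components` are
#'   starting/fixed structure only, all three are re-estimated in step 1.
#' @param delay_trough_ms,delay_peak_ms Visual onsets of the two conditions.
#' @param ... Passed on to [fit_component_amplitudes()] grid settings.
#' @return List with `g`, `amplitudes` (step-1 estimates), `r_squared_trough`,
#'   `r_squared_peak`.
#' @export
estimate_visual_gain <- function(trough_curve, peak_curve,
                                 components = model_components(),
                                 hrf = hrf_params(),
                                 delay_trough_ms = 70, delay_peak_ms = 150,
                                 ...) {
  if (length(trough_curve) != length(peak_curve)) {
    abort_input("trough and peak curves must share the lag grid")
  }
  fit1 <- fit_component_amplitudes(trough_curve, components, hrf,
                                   free = c("a_ramp", "a_box", "a_vis"),
                                   delay_ms = delay_trough_ms, gain = 1, ...)
  est <- fit1$estimates
  if (abs(est[["a_vis"]]) < 1e-12) {
    abort_singular("degenerate trough fit: a_vis is zero, gain unidentified")
  }
  cmp2 <- components
  cmp2$a_ramp <- est[["a_ramp"]]
  cmp2$a_box <- est[["a_box"]]
  cmp2$a_vis <- est[["a_vis"]]
  fit2 <- fit_component_amplitudes(peak_curve, cmp2, hrf, free = "g",
                                   delay_ms = delay_peak_ms, ...)
  list(g = unname(fit2$estimates[["g"]]),
       amplitudes = est,
       r_squared_trough = fit1$r_squared,
       r_squared_peak = fit2$r_squared)
}
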