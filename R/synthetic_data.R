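# Synthetic-data generator: behavioral trial tables and two-ROI event-related
# BOLD runs with the statistical structure the downstream analyses assume.
#
# Behavioral trials are Bernoulli outcomes whose success probability is
# sinusoidally modulated over the visuo-motor delay (theta range, phase-locked
# to action onset). BOLD runs are built from the forward model: per event, the
# condition lag curve for each ROI (V1 receives the visual delta with a
# delay-dependent gain; M1 only ramp + boxcar), plus linear drift, independent
# white noise, and an event-gated shared-noise component whose gain depends on
# the delay condition (the mechanism behind delay-dependent residual
# connectivity).

#' Generator configuration
#'
#' The defaults restate the experimental design this generator emulates:
#' behavioral delays uniform on 0--600 ms in 10 ms steps; fMRI runs of 130 TRs
#' at TR = 3 s with stimuli every 19 s on average (SD 3 s, at least 15 s
#' between keypresses) at four visuo-motor delays (70, 150, 230, 310 ms).
#'
#' @param seed Integer seed; every generator call derives its stream from it.
#' @param n_trials Number of behavioral trials.
#' @param baseline_acc Baseline probability correct.
#' @param osc_amp Amplitude of the sinusoidal accuracy modulation
#'   (probability units); `baseline_acc` +/- `osc_amp` must stay in \[0, 1\].
#' @param osc_freq_hz Oscillation frequency in Hz.
#' @param osc_phase_rad Oscillation phase at delay 0 (radians).
#' @param delay_min_ms,delay_max_ms,delay_step_ms Behavioral delay grid (ms).
#' @param n_runs Number of BOLD runs.
#' @param tr_s Repetition time in seconds.
#' @param run_len_tr TRs per run.
#' @param mean_gap_s,sd_gap_s,min_gap_s Event-gap distribution: truncated
#'   normal with this mean/SD, floored at `min_gap_s` (and never below 5 TRs).
#' @param delays_ms Condition delays used in the BOLD experiment (ms).
#' @param delay_weights Optional sampling weights over `delays_ms` (supports
#'   the 17/17/13/13 trial-count asymmetry); default uniform.
#' @param noise_sd SD of independent white noise per ROI (percent BOLD).
#' @param drift_slope Linear drift per TR (percent BOLD).
#' @param shared_sd SD of the shared (common to both ROIs) noise source.
#' @param shared_gain_by_delay Named multiplier applied to the shared noise
#'   within the -3..+12 s window around each event, per delay condition.
#' @param visual_gain_by_delay Named visual delta gain per delay condition
#'   (peak delays default to the fitted 1.33, trough delays to 1).
#' @param baseline_bold Raw-signal baseline. The generator composes signal,
#'   drift and noise on the percent-BOLD scale; with the default `0` that
#'   scale is emitted directly (ready for GLM fitting, exact-recovery tests).
#'   A positive value emits scanner-like raw series
#'   `baseline_bold * (1 + pct / 100)`, to be run through [preprocess_bold()].
#' @param model A [model_components()] object.
#' @param hrf An [hrf_params()] object.
#' @param subject_id Subject label written into trial tables.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_trials = 1000L,
                             baseline_acc = 0.7,
                             osc_amp = 0.1,
                             osc_freq_hz = 5.4,
                             osc_phase_rad = 0,
                             delay_min_ms = 0, delay_max_ms = 600,
                             delay_step_ms = 10,
                             n_runs = 1L, tr_s = 3, run_len_tr = 130L,
                             mean_gap_s = 19, sd_gap_s = 3, min_gap_s = 15,
                             delays_ms = c(70, 150, 230, 310),
                             delay_weights = NULL,
                             noise_sd = 0.5, drift_slope = 0.005,
                             shared_sd = 0.5,
                             shared_gain_by_delay = c("70" = 1, "150" = 1.2,
                                                      "230" = 1, "310" = 1.2),
                             visual_gain_by_delay = c("70" = 1, "150" = 1.33,
                                                      "230" = 1, "310" = 1.33),
                             baseline_bold = 0,
                             model = model_components(),
                             hrf = hrf_params(),
                             subject_id = "s01") {
  if (!.is_count(seed + 1)) abort_config("seed must be an integer")
  if (!.is_count(n_trials)) abort_config("n_trials must be a positive count")
  if (!.is_prob(baseline_acc)) abort_config("baseline_acc must be in [0,1]")
  if (!.is_number(osc_amp) || osc_amp < 0 || osc_amp > 1) {
    abort_config("osc_amp must be in [0,1]")
  }
  if (baseline_acc + osc_amp > 1 || baseline_acc - osc_amp < 0) {
    abort_config("baseline_acc +/- osc_amp must stay within [0,1]")
  }
  if (delay_max_ms <= delay_min_ms || delay_step_ms <= 0) {
    abort_config("delay grid must satisfy min < max with positive step")
  }
  if (!.is_count(n_runs)) abort_config("n_runs must be a positive count")
  if (!.is_number(tr_s) || tr_s <= 0) abort_config("tr_s must be > 0")
  if (!.is_count(run_len_tr) || run_len_tr <= 13) {
    abort_config("run_len_tr too short for preprocessing plus one event window")
  }
  if (length(delays_ms) < 1) abort_config("delays_ms must be non-empty")
  if (!is.null(delay_weights) && length(delay_weights) != length(delays_ms)) {
    abort_config("delay_weights must match delays_ms")
  }
  need <- as.character(delays_ms)
  if (!all(need %in% names(shared_gain_by_delay)) ||
      !all(need %in% names(visual_gain_by_delay))) {
    abort_config("gain maps must name every delay in delays_ms")
  }
  if (noise_sd < 0 || shared_sd < 0) abort_config("noise SDs must be >= 0")
  cfg <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
              baseline_acc = baseline_acc, osc_amp = osc_amp,
              osc_freq_hz = osc_freq_hz, osc_phase_rad = osc_phase_rad,
              delay_min_ms = delay_min_ms, delay_max_ms = delay_max_ms,
              delay_step_ms = delay_step_ms,
              n_runs = as.integer(n_runs), tr_s = tr_s,
              run_len_tr = as.integer(run_len_tr),
              mean_gap_s = mean_gap_s, sd_gap_s = sd_gap_s,
              min_gap_s = max(min_gap_s, 5 * tr_s),
              delays_ms = delays_ms, delay_weights = delay_weights,
              noise_sd = noise_sd, drift_slope = drift_slope,
              shared_sd = shared_sd,
              shared_gain_by_delay = shared_gain_by_delay,
              visual_gain_by_delay = visual_gain_by_delay,
              baseline_bold = baseline_bold,
              model = model, hrf = hrf, subject_id = subject_id)
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed %d | %d trials (f = %g Hz, amp = %g) | %d run(s) x %d TR\n",
              x$seed, x$n_trials, x$osc_freq_hz, x$osc_amp, x$n_runs,
              x$run_len_tr))
  invisible(x)
}

#' Generate behavioral trials with sinusoidally modulated accuracy
#'
#' Each trial draws a delay uniformly (or by `delay_weights`... over the full
#' behavioral grid) and a Bernoulli outcome with
#' p(d) = baseline + amp * sin(2 pi f d / 1000 + phase).
#'
#' @param cfg A [generator_config()].
#' @return A `data.frame` (class `trial_table`) with columns `subject_id`,
#'   `delay_ms`, `correct`.
#' @export
gen_behavior_trials <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- seq(cfg$delay_min_ms, cfg$delay_max_ms, by = cfg$delay_step_ms)
  if (length(grid) == 0) abort_config("empty delay grid")
  set.seed(cfg$seed)
  d <- sample(grid, cfg$n_trials, replace = TRUE)
  p <- cfg$baseline_acc +
    cfg$osc_amp * sin(2 * pi * cfg$osc_freq_hz * d / 1000 + cfg$osc_phase_rad)
  correct <- stats::rbinom(cfg$n_trials, 1L, p)
  out <- data.frame(subject_id = cfg$subject_id, delay_ms = d,
                    correct = correct, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Generate an event schedule for the BOLD runs
#'
#' Onsets accumulate truncated-normal gaps (mean `mean_gap_s`, SD `sd_gap_s`,
#' floor `min_gap_s` >= 5 TRs) from the run start; the continuous gaps leave
#' the onset phase within the TR approximately uniform. Each event gets a
#' delay condition; no event is placed within the last 7 TRs of a run. The
#' event TR index is the (0-based) TR containing the keypress.
#'
#' @param cfg A [generator_config()].
#' @return A `data.frame` (class `event_table`) with columns `run_id`,
#'   `onset_s`, `duration_s`, `trial_type` (e.g. `"d150"`), `delay_ms`,
#'   `event_tr`.
#' @export
gen_event_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1001L)
  run_dur <- cfg$run_len_tr * cfg$tr_s
  last_ok_tr <- cfg$run_len_tr - 8L  # leave 7 full TRs after the event TR
  rows <- list()
  for (r in seq_len(cfg$n_runs)) {
    onsets <- numeric(0)
    t <- rtruncnorm_lower(1, cfg$mean_gap_s / 2, cfg$sd_gap_s, cfg$tr_s)
    repeat {
      tr <- floor(t / cfg$tr_s)
      if (tr > last_ok_tr || t >= run_dur) break
      onsets <- c(onsets, t)
      t <- t + rtruncnorm_lower(1, cfg$mean_gap_s, cfg$sd_gap_s, cfg$min_gap_s)
    }
    if (length(onsets) == 0) {
      abort_config(sprintf("run %d too short to place any event", r))
    }
    dl <- sample(cfg$delays_ms, length(onsets), replace = TRUE,
                 prob = cfg$delay_weights)
    rows[[r]] <- data.frame(run_id = r, onset_s = onsets, duration_s = 0.033,
                            trial_type = paste0("d", dl), delay_ms = dl,
                            event_tr = floor(onsets / cfg$tr_s),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Generate two-ROI BOLD time series from an event schedule
#'
#' Per run and ROI, the series is the sum over events of the forward-model
#' condition curve (V1: ramp + boxcar + visual delta with the delay-dependent
#' gain; M1: ramp + boxcar only) placed at the event TR, plus linear drift,
#' independent white noise, and a shared noise source added identically to
#' both ROIs after being multiplied, within the -3..+12 s window around each
#' event, by `shared_gain_by_delay` of that event's condition.
#'
#' @param events An `event_table` from [gen_event_schedule()].
#' @param cfg The same [generator_config()].
#' @return A `data.frame` (class `bold_table`) with columns `run_id`,
#'   `tr_index` (0-based), `roi`, `value`, carrying the injected ground truth
#'   in `attr(, "ground_truth")` (per-delay V1 and M1 lag curves, gains and
#'   noise levels) for recovery tests.
#' @export
gen_roi_timeseries <- function(events, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!all(c("run_id", "event_tr", "delay_ms") %in% names(events))) {
    abort_input("events must carry run_id, event_tr, delay_ms")
  }
  set.seed(cfg$seed + 2002L)
  window <- 7L
  delays <- sort(unique(events$delay_ms))
  v1_curves <- lapply(delays, function(d) {
    g <- unname(cfg$visual_gain_by_delay[[as.character(d)]])
    simulate_condition(cfg$model, cfg$hrf, "va_trough", delay_ms = d,
                       gain = g, tr_s = cfg$tr_s, n_lags = window)$lag_values
  })
  names(v1_curves) <- as.character(delays)
  m1_curve <- simulate_condition(cfg$model, cfg$hrf, "action_only",
                                 tr_s = cfg$tr_s, n_lags = window)$lag_values
  L <- cfg$run_len_tr
  gate_offsets <- -1:4  # -3 .. +12 s at TR = 3 s
  rows <- vector("list", cfg$n_runs * 2L)
  k <- 0L
  for (r in seq_len(cfg$n_runs)) {
    ev <- events[events$run_id == r, , drop = FALSE]
    signal_v1 <- signal_m1 <- numeric(L)
    for (i in seq_len(nrow(ev))) {
      tr0 <- ev$event_tr[i]
      idx <- tr0 + seq_len(window) # 1-based rows tr0 .. tr0+6
      if (any(idx > L)) {
        abort_config(sprintf("event at TR %d leaves no 7-TR window in run %d",
                             tr0, r))
      }
      dchr <- as.character(ev$delay_ms[i])
      if (is.null(v1_curves[[dchr]])) abort_config("unknown delay in events")
      signal_v1[idx] <- signal_v1[idx] + v1_curves[[dchr]]
      signal_m1[idx] <- signal_m1[idx] + m1_curve
    }
    drift <- cfg$drift_slope * (seq_len(L) - 1L)
    shared <- stats::rnorm(L, 0, cfg$shared_sd)
    for (i in seq_len(nrow(ev))) {
      g <- unname(cfg$shared_gain_by_delay[[as.character(ev$delay_ms[i])]])
      idx <- ev$event_tr[i] + gate_offsets + 1L
      idx <- idx[idx >= 1L & idx <= L]
      shared[idx] <- shared[idx] * g
    }
    v1 <- signal_v1 + drift + shared + stats::rnorm(L, 0, cfg$noise_sd)
    m1 <- signal_m1 + drift + shared + stats::rnorm(L, 0, cfg$noise_sd)
    if (cfg$baseline_bold > 0) {
      v1 <- cfg$baseline_bold * (1 + v1 / 100)
      m1 <- cfg$baseline_bold * (1 + m1 / 100)
    }
    rows[[k <- k + 1L]] <- data.frame(run_id = r, tr_index = 0:(L - 1L),
                                      roi = "V1", value = v1,
                                      stringsAsFactors = FALSE)
    rows[[k <- k + 1L]] <- data.frame(run_id = r, tr_index = 0:(L - 1L),
                                      roi = "M1", value = m1,
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    v1_lag_curves = v1_curves, m1_lag_curve = m1_curve,
    visual_gain_by_delay = as.list(cfg$visual_gain_by_delay),
    shared_gain_by_delay = as.list(cfg$shared_gain_by_delay),
    noise_sd = cfg$noise_sd, shared_sd = cfg$shared_sd,
    drift_slope = cfg$drift_slope)
  class(out) <- c("bold_table", "data.frame")
  out
}

#' Write a fixture bundle (trials, events, BOLD, ground truth, manifest)
#'
#' @param trials,events,bold Generated tables from one seed.
#' @param cfg The [generator_config()] that produced them.
#' @param path Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(trials, events, bold, cfg, path) {
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort_io(sprintf("cannot create %s", path))
  write_tsv(trials, file.path(path, "trials.tsv"))
  write_tsv(events, file.path(path, "events.tsv"))
  write_tsv(bold, file.path(path, "bold.tsv"))
  gt <- attr(bold, "ground_truth")
  if (!is.null(gt)) write_json_file(gt, file.path(path, "ground_truth.json"))
  manifest <- list(seed = cfg$seed, config_hash = config_hash(unclass(cfg)),
                   n_trials = nrow(trials), n_events = nrow(events),
                   files = c("trials.tsv", "events.tsv", "bold.tsv",
                             "ground_truth.json"))
  write_json_file(manifest, file.path(path, "manifest.json"))
  invisible(manifest)
}

#' Read back a fixture bundle
#'
#' @param path Bundle directory.
#' @param expect_seed If given and different from the manifest seed, a
#'   fixture-mismatch warning is raised.
#' @return List with `trials`, `events`, `bold`, `ground_truth`, `manifest`.
#' @export
read_fixture_bundle <- function(path, expect_seed = NULL) {
  manifest <- read_json_file(file.path(path, "manifest.json"))
  if (!is.null(expect_seed) && !identical(as.integer(expect_seed),
                                          as.integer(manifest$seed))) {
    warning(sprintf("fixture mismatch: manifest seed %s, expected %s",
                    manifest$seed, expect_seed), call. = FALSE)
  }
  gt_path <- file.path(path, "ground_truth.json")
  list(trials = read_tsv(file.path(path, "trials.tsv")),
       events = read_tsv(file.path(path, "events.tsv")),
       bold = read_tsv(file.path(path, "bold.tsv")),
       ground_truth = if (file.exists(gt_path)) read_json_file(gt_path),
       manifest = manifest)
}

#' Onset phase of each event within the TR
#'
#' @param events An `event_table`.
#' @param tr_s Repetition time in seconds.
#' @return Phases in radians in `[0, 2 pi)`, one per event.
#' @export
event_phases <- function(events, tr_s = 3) {
  2 * pi * ((events$onset_s %% tr_s) / tr_s)
}
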