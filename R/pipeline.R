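# Pipeline orchestration: simulate -> behavior -> glm -> connectivity ->
# model, as one reproducible run with a flat config, per-stage logging and a
# machine-readable summary.

.pipeline_defaults <- function() {
  list(seed = 1L,
       out_dir = "oscivm_out",
       # simulate
       n_subjects = 7L, trials_per_subject = 1000L,
       baseline_acc = 0.7, osc_amp = 0.1, osc_freq_hz = 5.4,
       osc_phase_rad = 0,
       n_runs = 4L, run_len_tr = 130L, tr_s = 3,
       noise_sd = 0.3, shared_sd = 0.5, drift_slope = 0.005,
       min_iti_s = 1,
       # behavior
       f_min = 2, f_max = 20, f_step = 0.1, bin_width_ms = 20,
       n_perm = 1000L, subject_glm_freq_hz = 5.4,
       # glm
       align = "keypress", n_drop_tr = 6L, window_tr = 7L,
       # connectivity
       n_boot = 2000L,
       # report
       make_plots = FALSE, check = FALSE)
}

#' Read a flat key = value run configuration
#'
#' Lines of `key = value` (INI-style; `#` comments and `[section]` headers
#' are ignored, sections being purely decorative). Values are parsed as
#' numbers, logicals, or comma-separated numeric vectors where possible.
#' Unknown keys raise a configuration error.
#'
#' @param path Config file path.
#' @return A complete config list (defaults overridden by the file).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  cfg <- .pipeline_defaults()
  lines <- readLines(path, warn = FALSE)
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "" || grepl("^\\[", ln)) next
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort_config(sprintf("cannot parse config line: %s", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg)) abort_config(sprintf("unknown config key: %s", key))
    parsed <- if (grepl(",", val)) {
      as.numeric(strsplit(val, ",")[[1]])
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else {
      gsub('^"|"$', "", val)
    }
    cfg[[key]] <- parsed
  }
  cfg
}

#' Drop trials with too-short inter-trial intervals
#'
#' Mirrors the exclusion of trials initiated less than `min_iti_s` after the
#' previous keypress. Applied only when the trial table carries an `iti_s`
#' column; tables without one are returned untouched.
#'
#' @param trials A `trial_table`, optionally with an `iti_s` column.
#' @param min_iti_s Minimum allowed inter-trial interval in seconds.
#' @return The filtered table, with the excluded count in
#'   `attr(, "n_excluded")`.
#' @export
filter_trials_by_iti <- function(trials, min_iti_s = 1) {
  if (!"iti_s" %in% names(trials)) {
    attr(trials, "n_excluded") <- 0L
    return(trials)
  }
  keep <- is.na(trials$iti_s) | trials$iti_s >= min_iti_s
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .oscivm_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  "oscivm_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Simulates a behavioral aggregate and a two-ROI BOLD dataset, then runs the
#' oscillation scan with permutation correction, the per-subject sine GLM and
#' Hotelling test, the FIR deconvolution and amplitude summary, the residual
#' connectivity with bootstrap, and the forward-model gain fit on the
#' estimated beta curves. Writes `summary.json` (deterministic under a fixed
#' config: no timestamps) and a human-readable `report.txt` under
#' `config$out_dir`.
#'
#' @param config A config list (see [read_run_config()]); missing fields are
#'   filled with defaults.
#' @param stages Character vector of stages to run; default all of
#'   `c("simulate", "behavior", "glm", "connectivity", "model")`. Later
#'   stages require the earlier ones in the same call.
#' @return Invisibly, the summary list (with `checks` when `config$check`).
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "behavior", "glm",
                                    "connectivity", "model")) {
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  # out_dir is a path, not part of the analysis identity
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  summary <- list(seed = cfg$seed, config_hash = hash, stages = stages)
  data_dir <- file.path(out_dir, "data")

  sim <- NULL
  if ("simulate" %in% stages) {
    sim <- .stage("simulate", {
      trials_all <- list()
      for (s in seq_len(cfg$n_subjects)) {
        gc_s <- generator_config(seed = cfg$seed + s,
                                 n_trials = cfg$trials_per_subject,
                                 baseline_acc = cfg$baseline_acc,
                                 osc_amp = cfg$osc_amp,
                                 osc_freq_hz = cfg$osc_freq_hz,
                                 osc_phase_rad = cfg$osc_phase_rad,
                                 subject_id = sprintf("s%02d", s))
        trials_all[[s]] <- gen_behavior_trials(gc_s)
      }
      trials <- do.call(rbind, trials_all)
      class(trials) <- c("trial_table", "data.frame")
      trials <- filter_trials_by_iti(trials, cfg$min_iti_s)
      if (attr(trials, "n_excluded") > 0) {
        logf("simulate: excluded %d trials with ITI < %g s",
             attr(trials, "n_excluded"), cfg$min_iti_s)
      }
      gc_bold <- generator_config(seed = cfg$seed, n_runs = cfg$n_runs,
                                  run_len_tr = cfg$run_len_tr,
                                  tr_s = cfg$tr_s, noise_sd = cfg$noise_sd,
                                  shared_sd = cfg$shared_sd,
                                  drift_slope = cfg$drift_slope,
                                  baseline_bold = 1000)
      events <- gen_event_schedule(gc_bold)
      bold <- gen_roi_timeseries(events, gc_bold)
      write_fixture_bundle(trials, events, bold, gc_bold, data_dir)
      logf("simulate: %d trials, %d events, %d runs", nrow(trials),
           nrow(events), cfg$n_runs)
      list(trials = trials, events = events, bold = bold, cfg_bold = gc_bold)
    })
    summary$simulate <- list(n_trials = nrow(sim$trials),
                             n_events = nrow(sim$events))
  }

  if ("behavior" %in% stages) {
    if (is.null(sim)) abort_config("behavior stage requires simulate")
    beh <- .stage("behavior", {
      perm <- permutation_corrected_pvalue(sim$trials, cfg$f_min, cfg$f_max,
                                           cfg$f_step, cfg$bin_width_ms,
                                           n_perm = cfg$n_perm,
                                           seed = cfg$seed)
      betas <- t(vapply(split(sim$trials, sim$trials$subject_id),
                        subject_sine_glm, numeric(2),
                        freq_hz = cfg$subject_glm_freq_hz))
      hot <- hotelling_t2_test(betas)
      list(perm = perm, hotelling = hot)
    })
    summary$behavior <- list(
      best_freq_hz = beh$perm$observed_best$freq_hz,
      r_squared = beh$perm$observed_best$r_squared,
      amplitude = beh$perm$observed_best$amplitude,
      phase_rad = beh$perm$observed_best$phase_rad,
      p_corrected = beh$perm$p_corrected,
      exceeds_95th = beh$perm$exceeds_95th,
      hotelling_t2 = beh$hotelling$t2,
      hotelling_p = beh$hotelling$p_value)
    logf("behavior: best f = %.2f Hz, p = %.4g",
         summary$behavior$best_freq_hz, summary$behavior$p_corrected)
  }

  fits <- NULL; events_pp <- NULL
  if ("glm" %in% stages) {
    if (is.null(sim)) abort_config("glm stage requires simulate")
    g <- .stage("glm", {
      bold_pp <- preprocess_bold(sim$bold, cfg$n_drop_tr)
      ev <- withCallingHandlers(
        adjust_events_for_preprocessing(sim$events, cfg$n_drop_tr, cfg$tr_s),
        warning = function(w) {
          logf("glm: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      keep <- ev$event_tr + cfg$window_tr <= cfg$run_len_tr - cfg$n_drop_tr
      if (any(!keep)) logf("glm: dropped %d events too close to run end",
                           sum(!keep))
      ev <- ev[keep, , drop = FALSE]
      fit_v1 <- fit_fir_glm(bold_pp, ev, "V1", cfg$window_tr)
      fit_m1 <- fit_fir_glm(bold_pp, ev, "M1", cfg$window_tr)
      amp <- response_amplitude(fit_v1)
      ray <- rayleigh_uniformity(event_phases(ev, cfg$tr_s))
      list(fit_v1 = fit_v1, fit_m1 = fit_m1, amp = amp, ray = ray,
           events = ev)
    })
    fits <- g; events_pp <- g$events
    summary$glm <- list(r_squared_v1 = g$fit_v1$r_squared,
                        r_squared_m1 = g$fit_m1$r_squared,
                        amplitudes = as.list(g$amp),
                        rayleigh_p = g$ray$p,
                        betas_v1 = as.data.frame(g$fit_v1$betas),
                        betas_m1 = as.data.frame(g$fit_m1$betas))
    write_tsv(data.frame(roi = "V1",
                         trial_type = rownames(g$fit_v1$betas),
                         g$fit_v1$betas, check.names = FALSE),
              file.path(out_dir, "betas_v1.tsv"))
    logf("glm: V1 R^2 = %.3f, M1 R^2 = %.3f", g$fit_v1$r_squared,
         g$fit_m1$r_squared)
  }

  if ("connectivity" %in% stages) {
    if (is.null(fits)) abort_config("connectivity stage requires glm")
    conn <- .stage("connectivity", {
      epochs <- extract_residual_epochs(fits$fit_v1, fits$fit_m1, events_pp)
      est <- delay_connectivity(epochs)
      boot <- bootstrap_peak_vs_trough(epochs, n_boot = cfg$n_boot,
                                       seed = cfg$seed)
      trw <- trwise_connectivity_difference(epochs, n_boot = min(cfg$n_boot, 2000L),
                                            seed = cfg$seed)
      list(est = est, boot = boot, trw = trw)
    })
    summary$connectivity <- list(
      mean_r = as.list(conn$est$mean_r),
      peak_minus_trough = conn$boot$statistic,
      bootstrap_p = conn$boot$p,
      n_boot = conn$boot$n_boot,
      trwise = conn$trw)
    logf("connectivity: diff = %.4f, p = %.4g", conn$boot$statistic,
         conn$boot$p)
  }

  if ("model" %in% stages) {
    if (is.null(fits)) abort_config("model stage requires glm")
    mod <- .stage("model", {
      B <- fits$fit_v1$betas
      trough <- colMeans(B[c("d70", "d230"), , drop = FALSE])
      peak <- colMeans(B[c("d150", "d310"), , drop = FALSE])
      estimate_visual_gain(trough, peak, tr_s = cfg$tr_s)
    })
    summary$model <- list(gain = mod$g,
                          amplitudes = as.list(mod$amplitudes),
                          r_squared_trough = mod$r_squared_trough,
                          r_squared_peak = mod$r_squared_peak)
    logf("model: estimated visual gain = %.3f", mod$g)
  }

  if (isTRUE(cfg$check)) {
    checks <- list(
      behavior_detected = !is.null(summary$behavior) &&
        summary$behavior$p_corrected < 0.05 &&
        abs(summary$behavior$best_freq_hz - cfg$osc_freq_hz) <= 0.3,
      connectivity_detected = !is.null(summary$connectivity) &&
        summary$connectivity$bootstrap_p < 0.05,
      gain_recovered = !is.null(summary$model) &&
        summary$model$gain > 1)
    checks$all_pass <- all(unlist(checks))
    summary$checks <- checks
  }

  write_json_file(summary, file.path(out_dir, "summary.json"))
  .write_report(summary, file.path(out_dir, "report.txt"))
  invisible(summary)
}

.write_report <- function(s, path) {
  lines <- c("oscivm pipeline report",
             sprintf("seed %d | config %s", s$seed, s$config_hash), "")
  if (!is.null(s$behavior)) {
    lines <- c(lines, "Behavioral oscillation:",
               sprintf("  best frequency %.2f Hz, R^2 = %.3f, amplitude %.4f",
                       s$behavior$best_freq_hz, s$behavior$r_squared,
                       s$behavior$amplitude),
               sprintf("  permutation-corrected p = %.4g (95th pct exceeded: %s)",
                       s$behavior$p_corrected, s$behavior$exceeds_95th),
               sprintf("  Hotelling T^2 = %.2f, p = %.4g",
                       s$behavior$hotelling_t2, s$behavior$hotelling_p), "")
  }
  if (!is.null(s$glm)) {
    amps <- unlist(s$glm$amplitudes)
    lines <- c(lines, "FIR deconvolution (V1):",
               sprintf("  R^2 = %.3f (M1: %.3f), Rayleigh p = %.3f",
                       s$glm$r_squared_v1, s$glm$r_squared_m1,
                       s$glm$rayleigh_p),
               paste0("  3-12 s amplitude by delay: ",
                      paste(sprintf("%s = %.3f", names(amps), amps),
                            collapse = ", ")), "")
  }
  if (!is.null(s$connectivity)) {
    mr <- unlist(s$connectivity$mean_r)
    lines <- c(lines, "V1-M1 residual connectivity:",
               paste0("  mean r by delay: ",
                      paste(sprintf("%s = %.3f", names(mr), mr),
                            collapse = ", ")),
               sprintf("  peak - trough = %.4f, bootstrap one-tailed p = %.4g",
                       s$connectivity$peak_minus_trough,
                       s$connectivity$bootstrap_p), "")
  }
  if (!is.null(s$model)) {
    lines <- c(lines, "Forward-model fit to estimated V1 responses:",
               sprintf("  visual gain g = %.3f (trough R^2 = %.3f, peak R^2 = %.3f)",
                       s$model$gain, s$model$r_squared_trough,
                       s$model$r_squared_peak), "")
  }
  writeLines(lines, path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate | behavior | glm | connectivity | model | all`,
#' each taking `--config <file>` (flat key = value) and/or individual
#' `--key value` overrides (e.g. `--seed 7 --out_dir out`). `behavior` also
#' accepts `--trials <tsv>` to analyze an existing trial table.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the stage output; called for side effects.
#' @export
oscivm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: oscivm <simulate|behavior|glm|connectivity|model|all> [--config file] [--key value ...]\n")
    return(invisible(NULL))
  }
  sub <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    if (!grepl("^--", args[i]) || i == length(args)) {
      abort_config(sprintf("cannot parse argument '%s'", args[i]))
    }
    key <- sub("^--", "", args[i])
    val <- args[i + 1L]
    num <- suppressWarnings(as.numeric(val))
    opts[[key]] <- if (!is.na(num)) num else val
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else .pipeline_defaults()
  extra <- opts[setdiff(names(opts), c("config", "trials"))]
  known <- intersect(names(extra), names(cfg))
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown)) abort_config(paste("unknown option(s):",
                                          paste(unknown, collapse = ", ")))
  cfg[known] <- extra[known]

  if (sub == "behavior" && !is.null(opts$trials)) {
    trials <- read_tsv(opts$trials)
    perm <- permutation_corrected_pvalue(trials, cfg$f_min, cfg$f_max,
                                         cfg$f_step, cfg$bin_width_ms,
                                         n_perm = cfg$n_perm, seed = cfg$seed)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_file(list(best_freq_hz = perm$observed_best$freq_hz,
                         r_squared = perm$observed_best$r_squared,
                         p_corrected = perm$p_corrected,
                         n_perm = perm$n_perm, seed = perm$seed),
                    file.path(cfg$out_dir, "behavior.json"))
    print(perm)
    return(invisible(perm))
  }
  stages <- switch(sub,
                   all = c("simulate", "behavior", "glm", "connectivity", "model"),
                   simulate = "simulate",
                   behavior = c("simulate", "behavior"),
                   glm = c("simulate", "glm"),
                   connectivity = c("simulate", "glm", "connectivity"),
                   model = c("simulate", "glm", "model"),
                   abort_config(sprintf("unknown subcommand '%s'", sub)))
  out <- run_pipeline(cfg, stages)
  if (isTRUE(cfg$check) && !is.null(out$checks) && !out$checks$all_pass) {
    .oscivm_abort("pipeline checks failed", "oscivm_check_error")
  }
  invisible(out)
}
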