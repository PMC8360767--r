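# FIR deconvolution GLM for event-related ROI BOLD, plus the delay-modulation
# statistics: response-amplitude summaries (3-12 s integral / time), paired
# one-tailed contrasts with Holm correction, one-way repeated-measures ANOVA,
# and the Rayleigh test used to check event-timing homogeneity within the TR.

#' Preprocess a raw ROI BOLD series
#'
#' Drops the first `n_drop` TRs (steady-state), subtracts the OLS linear
#' trend, and converts to percent signal change by normalizing to the mean of
#' the retained raw series. Event TR indices must be shifted by `-n_drop`
#' accordingly (see [adjust_events_for_preprocessing()]).
#'
#' @param values Raw BOLD values of one run, in TR order.
#' @param n_drop Leading TRs to discard (default 6).
#' @return Numeric vector of percent-signal-change values.
#' @export
preprocess_roi_series <- function(values, n_drop = 6L) {
  if (length(values) <= n_drop) abort_input("run shorter than n_drop TRs")
  v <- values[-seq_len(n_drop)]
  m <- mean(v)
  if (abs(m) < 1e-12) abort_input("zero-mean series cannot be normalized")
  tt <- seq_along(v)
  fit <- stats::lm.fit(cbind(1, tt), v)
  100 * fit$residuals / m
}

#' Preprocess a long-format BOLD table per run and ROI
#'
#' @param bold A `bold_table` (`run_id`, `tr_index`, `roi`, `value`).
#' @param n_drop Leading TRs to discard per run.
#' @return A `bold_table` on the shortened, re-indexed TR grid.
#' @export
preprocess_bold <- function(bold, n_drop = 6L) {
  pieces <- split(bold, list(bold$run_id, bold$roi), drop = TRUE)
  out <- lapply(pieces, function(p) {
    p <- p[order(p$tr_index), , drop = FALSE]
    v <- preprocess_roi_series(p$value, n_drop)
    data.frame(run_id = p$run_id[1], tr_index = seq_along(v) - 1L,
               roi = p$roi[1], value = v, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bold_table", "data.frame")
  res
}

#' Shift events onto the preprocessed TR grid
#'
#' @param events An `event_table`.
#' @param n_drop TRs dropped by preprocessing.
#' @param tr_s Repetition time in seconds.
#' @return The event table with `event_tr` and `onset_s` shifted; events
#'   falling before the retained grid are removed with a warning.
#' @export
adjust_events_for_preprocessing <- function(events, n_drop = 6L, tr_s = 3) {
  ev <- events
  ev$event_tr <- ev$event_tr - n_drop
  ev$onset_s <- ev$onset_s - n_drop * tr_s
  dropped <- ev$event_tr < 0
  if (any(dropped)) {
    warning(sprintf("%d event(s) within the discarded initial TRs were removed",
                    sum(dropped)), call. = FALSE)
    ev <- ev[!dropped, , drop = FALSE]
  }
  ev
}

#' Build the FIR design matrix for one run
#'
#' One indicator column per (event type, lag 0..`window_tr - 1`) cell: an
#' event of type k at (0-based) TR t puts a 1 at rows t..t+6 of the k-th
#' type's lag columns. Entries are indicators, not counts: overlapping events
#' hitting the same cell are flagged with a warning rather than summed
#' (events are >= 15 s apart by design, so overlap marks a degenerate input).
#' A constant column is appended.
#'
#' @param events Events of a single run (needs `trial_type`, `event_tr`).
#' @param n_tr Number of TRs in the run.
#' @param window_tr FIR window length in TRs (default 7).
#' @param types Event types defining the column blocks; defaults to the
#'   sorted unique types present.
#' @return A `fir_design` matrix of size `n_tr x (window_tr * n_types + 1)`.
#' @export
build_fir_design <- function(events, n_tr, window_tr = 7L, types = NULL) {
  types <- types %||% sort(unique(events$trial_type))
  k <- length(types)
  X <- matrix(0, n_tr, window_tr * k + 1L)
  lag_names <- if (k > 0) {
    paste(rep(types, each = window_tr),
          paste0("lag", seq_len(window_tr) - 1L), sep = ":")
  } else {
    character(0)
  }
  colnames(X) <- c(lag_names, "constant")
  X[, ncol(X)] <- 1
  n_overlap <- 0L
  for (i in seq_len(nrow(events))) {
    t0 <- events$event_tr[i]
    if (t0 < 0 || t0 + window_tr > n_tr) {
      abort_input(sprintf(
        "event %d (type %s, TR %d) leaves no %d-TR window within the run",
        i, events$trial_type[i], t0, window_tr))
    }
    kk <- match(events$trial_type[i], types)
    if (is.na(kk)) abort_input(sprintf("unknown trial_type %s", events$trial_type[i]))
    cols <- (kk - 1L) * window_tr + seq_len(window_tr)
    rows <- t0 + seq_len(window_tr) # 1-based rows for TRs t0 .. t0+w-1
    cells <- cbind(rows, cols)
    n_overlap <- n_overlap + sum(X[cells] == 1)
    X[cells] <- 1
  }
  if (n_overlap > 0) {
    warning(sprintf("%d overlapping (type, lag) design cells kept as indicators",
                    n_overlap), call. = FALSE)
  }
  structure(X, class = c("fir_design", class(X)),
            types = types, window_tr = as.integer(window_tr))
}

#' Fit the FIR deconvolution GLM for one ROI
#'
#' Builds the per-run FIR blocks, concatenates runs, appends a single
#' constant, and solves by OLS. Residuals are returned per run for the
#' connectivity stage.
#'
#' @param bold A (preprocessed) `bold_table` containing the ROI.
#' @param events Events on the same TR grid as `bold`.
#' @param roi ROI name to fit.
#' @param window_tr FIR window length (default 7).
#' @param types Event types (default: sorted unique types in `events`).
#' @return Object of class `glm_fit` with `betas` (types x lags matrix),
#'   `constant`, `residuals` (list per run), `fitted`, `r_squared`,
#'   `n_timepoints`, `roi`, `types`, `window_tr`, `runs`.
#' @export
fit_fir_glm <- function(bold, events, roi, window_tr = 7L, types = NULL) {
  b <- bold[bold$roi == roi, , drop = FALSE]
  if (nrow(b) == 0) abort_input(sprintf("no BOLD rows for ROI %s", roi))
  runs <- sort(unique(b$run_id))
  if (!all(events$run_id %in% runs)) {
    abort_input("events reference run_ids absent from the BOLD table")
  }
  types <- types %||% sort(unique(events$trial_type))
  blocks <- list(); ys <- list()
  for (r in runs) {
    br <- b[b$run_id == r, , drop = FALSE]
    br <- br[order(br$tr_index), , drop = FALSE]
    er <- events[events$run_id == r, , drop = FALSE]
    Xr <- build_fir_design(er, nrow(br), window_tr, types)
    blocks[[as.character(r)]] <- Xr[, -ncol(Xr), drop = FALSE]
    ys[[as.character(r)]] <- br$value
  }
  X <- cbind(do.call(rbind, blocks), constant = 1)
  y <- unlist(ys, use.names = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort_singular(paste("rank-deficient FIR design; collinear columns:",
                         paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X %*% beta)
  resid <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 0
  betas <- matrix(beta[-length(beta)], nrow = length(types),
                  ncol = window_tr, byrow = TRUE,
                  dimnames = list(types, paste0("lag", seq_len(window_tr) - 1L)))
  lens <- vapply(ys, length, integer(1))
  idx_end <- cumsum(lens)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  res_by_run <- Map(function(s, e) resid[s:e], idx_start, idx_end)
  names(res_by_run) <- names(ys)
  structure(list(betas = betas, constant = unname(beta[length(beta)]),
                 residuals = res_by_run, fitted = fitted,
                 r_squared = r2, n_timepoints = length(y), roi = roi,
                 types = types, window_tr = as.integer(window_tr),
                 runs = runs),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> ROI %s | %d types x %d lags | R^2 = %.3f | n = %d\n",
              x$roi, nrow(x$betas), x$window_tr, x$r_squared, x$n_timepoints))
  invisible(x)
}

#' Response amplitude: integral of the response from 3 to 12 s divided by time
#'
#' Discretized at TR = 3 s as the mean of the lag-1..4 betas (rectangle rule);
#' `method = "trapezoid"` uses the trapezoid rule over the same interval.
#'
#' @param fit A `glm_fit` with a 7-lag window.
#' @param lags 1-based lag indices over which to integrate (default lags
#'   1..4, i.e. 3--12 s).
#' @param method `"mean"` (default) or `"trapezoid"`.
#' @return Named numeric vector, one amplitude per event type.
#' @export
response_amplitude <- function(fit, lags = 1:4, method = c("mean", "trapezoid")) {
  method <- match.arg(method)
  if (fit$window_tr < max(lags) + 1L) {
    abort_input(sprintf("window of %d lags cannot integrate lags %s",
                        fit$window_tr, paste(range(lags), collapse = "-")))
  }
  B <- fit$betas[, lags + 1L, drop = FALSE]
  if (method == "mean") {
    amp <- rowMeans(B)
  } else {
    nl <- ncol(B)
    w <- c(0.5, rep(1, nl - 2L), 0.5)
    amp <- as.vector(B %*% w) / (nl - 1L)
    names(amp) <- rownames(B)
  }
  amp
}

#' Paired one-tailed delay contrasts with Holm correction
#'
#' For each (peak, trough) pairing, a paired one-tailed t test of
#' amplitude(peak) > amplitude(trough); p values are Holm step-down adjusted
#' (monotone, capped at 1).
#'
#' @param amplitudes Subjects x conditions matrix with condition column names
#'   (e.g. `d70`, `d150`, `d230`, `d310`).
#' @param pairs List of `c(peak, trough)` column-name pairs; default the four
#'   canonical pairings (150 vs 70, 150 vs 230, 310 vs 230, 310 vs 70).
#' @return `data.frame` with `pair`, `t`, `df`, `p`, `p_holm`.
#' @export
delay_contrasts <- function(amplitudes,
                            pairs = list(c("d150", "d70"), c("d150", "d230"),
                                         c("d310", "d230"), c("d310", "d70"))) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) < 3) abort_input("need >= 3 subjects")
  res <- lapply(pairs, function(pr) {
    if (!all(pr %in% colnames(amplitudes))) {
      abort_input(sprintf("conditions %s absent from amplitude matrix",
                          paste(pr, collapse = ", ")))
    }
    d <- amplitudes[, pr[1]] - amplitudes[, pr[2]]
    if (stats::sd(d) == 0) {
      abort_input(sprintf("zero variance of paired differences for %s vs %s",
                          pr[1], pr[2]))
    }
    n <- length(d)
    tval <- mean(d) / (stats::sd(d) / sqrt(n))
    data.frame(pair = paste(pr[1], ">", pr[2]), t = tval, df = n - 1L,
               p = stats::pt(tval, n - 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' One-sample t test against zero
#'
#' @param x Numeric vector.
#' @param alternative As in [stats::t.test()].
#' @return List with `t`, `df`, `p`.
#' @export
one_sample_ttest <- function(x, alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (stats::sd(x) == 0) abort_input("zero variance")
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' One-way repeated-measures ANOVA over delay conditions
#'
#' Classical one-way within-subject decomposition with df
#' `(k - 1, (k - 1)(n - 1))` and partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param amplitudes Complete subjects x conditions matrix (no missing cells).
#' @return List with `f`, `df`, `p`, `eta_squared_partial`.
#' @export
rm_anova_delays <- function(amplitudes) {
  m <- as.matrix(amplitudes)
  if (anyNA(m)) abort_input("missing cells; repeated-measures ANOVA needs complete data")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) abort_input("need >= 3 subjects and >= 2 conditions")
  grand <- mean(m)
  ss_effect <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_effect - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  if (ss_effect <= 1e-14 * max(ss_total, 1)) {
    # no condition effect at all (covers the 0/0 case of identical columns)
    return(list(f = 0, df = c(df1, df2), p = 1, eta_squared_partial = 0))
  }
  f <- (ss_effect / df1) / (ss_error / df2)
  list(f = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       eta_squared_partial = ss_effect / (ss_effect + ss_error))
}

#' Rayleigh test of circular uniformity
#'
#' `Rbar` is the mean resultant length, `z = n Rbar^2`, and
#' `p = exp(-z) (1 + (2z - z^2) / (4n))`, clipped to `[0, 1]`. The p-value
#' approximation is accurate for n >= 5.
#'
#' @param phases_rad Phases in radians.
#' @return List with `rbar`, `z`, `p`, `n`.
#' @export
rayleigh_uniformity <- function(phases_rad) {
  n <- length(phases_rad)
  if (n == 0) abort_input("empty phase vector")
  rbar <- Mod(mean(exp(1i * phases_rad)))
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  list(rbar = rbar, z = z, p = min(max(p, 0), 1), n = n)
}
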