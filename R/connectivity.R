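# M1-V1 functional connectivity from FIR-GLM residuals.
#
# Residual epochs are the residual values at TR offsets -1..4 relative to the
# event TR (-3 to +12 s at TR = 3 s). Per delay condition and offset, the
# Pearson correlation is computed across events between the two ROIs;
# averaging the six offset correlations gives the per-delay connectivity.
# Peak-vs-trough differences are tested by resampling events with replacement
# within each delay (one-tailed bootstrap).

#' Extract per-event residual epochs for two ROIs
#'
#' @param fit_a,fit_b `glm_fit` objects (e.g. V1 and M1) sharing runs and the
#'   TR grid of `events`.
#' @param events Events on the same (preprocessed) TR grid.
#' @param offsets TR offsets relative to the event TR (default `-1:4`).
#' @return Object of class `residual_epochs` with `delay_ms` (per event),
#'   matrices `a` and `b` (events x offsets), `offsets`, `n_dropped`.
#'   Events whose window crosses a run boundary are dropped and counted.
#' @export
extract_residual_epochs <- function(fit_a, fit_b, events, offsets = -1:4) {
  if (!identical(fit_a$runs, fit_b$runs)) {
    abort_input("the two GLM fits cover different runs")
  }
  rows_a <- list(); rows_b <- list(); delays <- numeric(0)
  n_dropped <- 0L
  for (i in seq_len(nrow(events))) {
    r <- as.character(events$run_id[i])
    ra <- fit_a$residuals[[r]]
    rb <- fit_b$residuals[[r]]
    if (is.null(ra) || is.null(rb)) abort_input(sprintf("no residuals for run %s", r))
    idx <- events$event_tr[i] + offsets + 1L # 1-based
    if (any(idx < 1L | idx > length(ra))) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows_a[[length(rows_a) + 1L]] <- ra[idx]
    rows_b[[length(rows_b) + 1L]] <- rb[idx]
    delays <- c(delays, events$delay_ms[i])
  }
  if (length(rows_a) == 0) abort_input("all events fell across run boundaries")
  structure(list(delay_ms = delays,
                 a = do.call(rbind, rows_a), b = do.call(rbind, rows_b),
                 offsets = offsets, n_dropped = n_dropped,
                 roi_a = fit_a$roi, roi_b = fit_b$roi),
            class = "residual_epochs")
}

# Pearson correlation per column (offset) across events; zero-variance
# columns yield r = 0 (with optional warning).
.offset_correlations <- function(A, B, warn = TRUE) {
  r <- vapply(seq_len(ncol(A)), function(j) {
    x <- A[, j]; y <- B[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      if (warn) warning("zero-variance residual vector; r set to 0", call. = FALSE)
      return(0)
    }
    stats::cor(x, y)
  }, numeric(1))
  r
}

#' Per-delay residual connectivity
#'
#' @param epochs A `residual_epochs` object.
#' @param min_events Minimum events required per delay (default 5).
#' @param fisher_z Average offset correlations on the Fisher-z scale before
#'   back-transforming (default `FALSE`: plain average).
#' @param tr_s Repetition time (for labeling offsets in seconds).
#' @return Object of class `connectivity_estimate` with `per_offset_r`
#'   (delays x offsets matrix), `mean_r` and `n_events` (named by delay),
#'   `offsets_s`.
#' @export
delay_connectivity <- function(epochs, min_events = 5L, fisher_z = FALSE,
                               tr_s = 3) {
  delays <- sort(unique(epochs$delay_ms))
  per <- matrix(NA_real_, length(delays), length(epochs$offsets),
                dimnames = list(paste0("d", delays),
                                paste0("off", epochs$offsets)))
  n_ev <- stats::setNames(integer(length(delays)), paste0("d", delays))
  for (i in seq_along(delays)) {
    sel <- epochs$delay_ms == delays[i]
    if (sum(sel) < min_events) {
      abort_input(sprintf("only %d events for delay %g ms (need >= %d)",
                          sum(sel), delays[i], min_events))
    }
    per[i, ] <- .offset_correlations(epochs$a[sel, , drop = FALSE],
                                     epochs$b[sel, , drop = FALSE])
    n_ev[i] <- sum(sel)
  }
  mean_r <- if (fisher_z) {
    tanh(rowMeans(atanh(pmin(pmax(per, -0.999999), 0.999999))))
  } else {
    rowMeans(per)
  }
  structure(list(per_offset_r = per, mean_r = mean_r, n_events = n_ev,
                 delays_ms = delays, offsets_s = epochs$offsets * tr_s,
                 fisher_z = fisher_z),
            class = "connectivity_estimate")
}

#' @export
print.connectivity_estimate <- function(x, ...) {
  cat("<connectivity_estimate>\n")
  for (i in seq_along(x$delays_ms)) {
    cat(sprintf("  %4g ms: mean r = %.3f (n = %d)\n", x$delays_ms[i],
                x$mean_r[i], x$n_events[i]))
  }
  invisible(x)
}

# Vectorized bootstrap of per-offset correlations for one delay group.
# V, M: events x offsets; idx: events x n_boot resample indices.
# Returns n_boot x offsets matrix of r (0 where a resample is degenerate).
.boot_offset_cor <- function(V, M, idx) {
  n <- nrow(idx)
  B <- ncol(idx)
  out <- matrix(0, B, ncol(V))
  for (j in seq_len(ncol(V))) {
    vb <- matrix(V[, j][idx], n, B)
    mb <- matrix(M[, j][idx], n, B)
    mv <- colMeans(vb); mm <- colMeans(mb)
    sv <- sqrt(colMeans(vb^2) - mv^2)
    sm <- sqrt(colMeans(mb^2) - mm^2)
    cov_ <- colMeans(vb * mb) - mv * mm
    denom <- sv * sm
    r <- ifelse(denom > 0, cov_ / denom, 0)
    out[, j] <- r
  }
  out
}

#' Bootstrap test of peak-vs-trough connectivity
#'
#' Statistic: mean_r over peak delays minus mean_r over trough delays (mean_r
#' averages the six offset correlations, then the delays within each group).
#' Events are resampled with replacement within each delay; the one-tailed p
#' is `(1 + #boot <= 0) / (n_boot + 1)`.
#'
#' @param epochs A `residual_epochs` object.
#' @param peak,trough Delay groups in ms.
#' @param n_boot Bootstrap repetitions (>= 100; default 10000).
#' @param seed RNG seed.
#' @return Object of class `bootstrap_result` with `statistic`, `boot`
#'   (vector of resampled differences), `p`, `n_boot`, `seed`.
#' @export
bootstrap_peak_vs_trough <- function(epochs, peak = c(150, 310),
                                     trough = c(70, 230), n_boot = 10000L,
                                     seed = 1L) {
  if (!.is_count(n_boot) || n_boot < 100) abort_config("n_boot must be >= 100")
  groups <- list(peak = peak, trough = trough)
  for (g in names(groups)) {
    if (!any(epochs$delay_ms %in% groups[[g]])) {
      abort_input(sprintf("no events in the %s group", g))
    }
  }
  est <- delay_connectivity(epochs)
  obs <- mean(est$mean_r[paste0("d", peak)]) -
    mean(est$mean_r[paste0("d", trough)])
  set.seed(seed)
  delays <- sort(unique(epochs$delay_ms))
  boot_by_delay <- list()
  for (d in delays) {
    sel <- which(epochs$delay_ms == d)
    idx <- matrix(sample(sel, length(sel) * n_boot, replace = TRUE),
                  length(sel), n_boot)
    # indices are into the full epoch matrices
    rb <- .boot_offset_cor(epochs$a, epochs$b, idx)
    boot_by_delay[[paste0("d", d)]] <- rowMeans(rb)
  }
  boot_group <- function(ds) {
    Reduce(`+`, boot_by_delay[paste0("d", ds)]) / length(ds)
  }
  boot <- boot_group(peak) - boot_group(trough)
  p <- (1 + sum(boot <= 0)) / (n_boot + 1)
  structure(list(statistic = obs, boot = boot, p = p,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 peak = peak, trough = trough),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> diff = %.4f | one-tailed p = %.4g (%d reps)\n",
              x$statistic, x$p, x$n_boot))
  invisible(x)
}

#' Per-offset peak-minus-trough correlation difference with bootstrap SEs
#'
#' For each TR offset, the peak-group correlation (average of the per-delay
#' correlations at that offset) minus the trough-group correlation, with a
#' bootstrap standard error from resampling events within delay.
#'
#' @inheritParams bootstrap_peak_vs_trough
#' @param tr_s Repetition time (for labeling offsets in seconds).
#' @return `data.frame` with `offset_s`, `difference`, `se_boot`.
#' @export
trwise_connectivity_difference <- function(epochs, peak = c(150, 310),
                                           trough = c(70, 230),
                                           n_boot = 2000L, seed = 1L,
                                           tr_s = 3) {
  est <- delay_connectivity(epochs)
  rp <- colMeans(est$per_offset_r[paste0("d", peak), , drop = FALSE])
  rt <- colMeans(est$per_offset_r[paste0("d", trough), , drop = FALSE])
  diff_obs <- rp - rt
  set.seed(seed)
  delays <- sort(unique(epochs$delay_ms))
  boot_by_delay <- list()
  for (d in delays) {
    sel <- which(epochs$delay_ms == d)
    idx <- matrix(sample(sel, length(sel) * n_boot, replace = TRUE),
                  length(sel), n_boot)
    boot_by_delay[[paste0("d", d)]] <- .boot_offset_cor(epochs$a, epochs$b, idx)
  }
  group_mat <- function(ds) {
    Reduce(`+`, boot_by_delay[paste0("d", ds)]) / length(ds)
  }
  boot_diff <- group_mat(peak) - group_mat(trough) # n_boot x offsets
  data.frame(offset_s = epochs$offsets * tr_s,
             difference = unname(diff_obs),
             se_boot = apply(boot_diff, 2L, stats::sd))
}
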