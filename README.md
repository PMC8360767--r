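# oscivm

Analysis and simulation of **action-locked theta oscillations** in behavior
and event-related BOLD. When a voluntary action (a keypress) phase-resets an
endogenous theta-range rhythm, visual discrimination accuracy and early
visual cortex (V1) responsiveness both oscillate as a function of the
**visuo-motor delay** — the interval between the keypress and the visual
stimulus. `oscivm` provides the full analysis chain for such experiments,
plus a synthetic-data generator that emulates their trial and BOLD structure
so every stage can be tested end to end without any scanner data.

Who it is for: researchers analyzing delay-resolved psychophysics and
ROI-level event-related fMRI (behavioral oscillation detection, FIR
deconvolution, residual functional connectivity, forward hemodynamic
modelling), and anyone needing a calibrated simulator of that design.

## The statistics at the core

**Behavioral oscillation.** Trials are binned over delay (20 ms bins) and
the proportion correct y(x) is fit at each frequency f of a scan grid
(2–20 Hz, 0.1 Hz steps) with

    y(x) = b0 + b1 sin(2 pi f x) + b2 cos(2 pi f x)

by OLS; amplitude = sqrt(b1^2 + b2^2), phase = atan2(b2, b1). Significance
of the best-fitting frequency is assessed by shuffling the correct/incorrect
labels, re-binning and re-scanning the full grid per surrogate: comparing
the observed max R^2 against the surrogate max-R^2 distribution corrects for
the frequency search automatically. Group-level phase consistency uses
per-subject single-trial sine/cosine regressions and Hotelling's T^2
(T^2 = n x̄' S^-1 x̄, F = T^2 (n-2) / (2(n-1)) ~ F(2, n-2)).

**FIR deconvolution.** Each event type contributes 7 indicator regressors
(lags 0..6 TRs after the event TR; TR = 3 s), so four delay conditions give
28 predictors plus a constant. OLS betas trace the hemodynamic response
without assuming its shape. Response amplitude is the integral of the
response from 3 to 12 s divided by time (the mean of lag-1..4 betas), tested
across subjects with paired one-tailed t tests (Holm-corrected) and a
repeated-measures ANOVA.

**Residual connectivity.** After subtracting the GLM prediction, V1 and M1
residuals are correlated across events at each TR offset in −3..+12 s around
the event; the six offset correlations are averaged per delay. Peak
(150/310 ms) minus trough (70/230 ms) connectivity is tested by resampling
events with replacement within delay (10,000 reps, one-tailed).

**Forward model.** Neural inputs — a motor-preparation ramp (−2 to −0.55 s),
a negative boxcar (−0.55 to +4 s) and a visual delta at the visuo-motor
delay — are convolved with a gamma-family hemodynamic kernel
h(t) ∝ ((t−δ)/τ)^(n−1) exp(−(t−δ)/τ) (τ = 2 s, n = 3, δ = 3 s). A single
multiplicative gain g on the delta (≈1.33 at peak delays) reproduces the
delay modulation; `estimate_visual_gain()` recovers it from trough/peak lag
curves.

## Worked example

```r
library(oscivm)

cfg    <- generator_config(seed = 3, n_trials = 7000, osc_amp = 0.1,
                           osc_freq_hz = 5.4, n_runs = 8,
                           noise_sd = 0.15, shared_sd = 0.5,
                           shared_gain_by_delay = c("70" = 1, "150" = 1.5,
                                                    "230" = 1, "310" = 1.5))
trials <- gen_behavior_trials(cfg)
perm   <- permutation_corrected_pvalue(trials, n_perm = 1000, seed = 3)
print(perm)
#> <perm_result> best f = 5.40 Hz, R^2 = 0.871 | p_corrected = 0.000999 (1000 perms)

events <- gen_event_schedule(cfg)
bold   <- gen_roi_timeseries(events, cfg)
fit_v1 <- fit_fir_glm(bold, events, "V1")
fit_m1 <- fit_fir_glm(bold, events, "M1")
round(response_amplitude(fit_v1), 3)
#>  d150  d230  d310   d70
#> 0.901 0.635 1.071 0.668

epochs <- extract_residual_epochs(fit_v1, fit_m1, events)
print(delay_connectivity(epochs))
#> <connectivity_estimate>
#>     70 ms: mean r = 0.926 (n = 48)
#>    150 ms: mean r = 0.961 (n = 37)
#>    230 ms: mean r = 0.928 (n = 36)
#>    310 ms: mean r = 0.947 (n = 32)
print(bootstrap_peak_vs_trough(epochs, n_boot = 10000, seed = 3))
#> <bootstrap_result> diff = 0.0270 | one-tailed p = 0.0004 (10000 reps)

B <- fit_v1$betas
g <- estimate_visual_gain(colMeans(B[c("d70", "d230"), ]),
                          colMeans(B[c("d150", "d310"), ]))
round(g$g, 3)
#> [1] 1.332
```

Reading the output: the permutation scan recovers the injected 5.4 Hz
accuracy oscillation with a corrected p of 1/1001; the 3–12 s V1 response
amplitudes are larger at the "peak" delays (150/310 ms, which carry the
injected 33% visual gain: 0.90/1.07 %BOLD) than at the "trough" delays
(70/230 ms: 0.67/0.64); V1–M1 residual connectivity is higher at the peak
delays, where this demo injects a 50% event-gated shared-noise gain
(one-tailed bootstrap p = 0.0004); and refitting the forward model to the
estimated beta curves recovers a visual gain of 1.332 against the injected
1.33.

A full run (simulate → behavior → glm → connectivity → model, with
`summary.json` and `report.txt`) is one call:

```r
run_pipeline(list(seed = 1, out_dir = "demo_out"))
```

or from the shell:

```sh
Rscript inst/cli/oscivm.R all --config run.ini
```

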