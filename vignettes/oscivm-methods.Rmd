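---
title: "Methods: models, parameters and design choices in oscivm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in oscivm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscivm)
```

# The scientific problem

A voluntary action can phase-reset endogenous theta-range (~4–8 Hz)
oscillations in sensory cortex. In a visuo-motor delay design, the observer
presses a key and a brief visual stimulus follows after a variable delay;
sweeping the delay samples successive phases of the action-locked rhythm.
Two observable consequences are modelled here: (1) discrimination accuracy
oscillates sinusoidally over delay; (2) the event-related BOLD response of
early visual cortex, and its residual coupling with motor cortex, are
modulated at the same rhythm. `oscivm` implements the analysis chain for
both observables and a generator that emulates the design.

# The behavioral model and its test

Binned accuracy is regressed on `[1, sin(2πfx), cos(2πfx)]` at every
frequency of an inclusive grid (default 2–20 Hz in 0.1 Hz steps, 181
frequencies; bin width 20 ms, bin center = left edge + width/2, in seconds
so f is in Hz). The (β1, β2) parameterization keeps the fit linear; the
amplitude/phase form `A sin(2πfx + φ)` is recovered as
`A = sqrt(β1² + β2²)`, `φ = atan2(β2, β1)`, and the equivalence is enforced
pointwise by a property test.

**Permutation correction.** Correct/incorrect labels are shuffled across
trials with delays fixed, the series re-binned, and the *full grid*
re-scanned per surrogate. Because each surrogate is allowed its best
frequency, amplitude and phase, the surrogate max-R² distribution already
embodies the multiplicity of the frequency search; the corrected p needs no
further adjustment. We use the add-one estimator
`p = (1 + #{null ≥ observed}) / (n_perm + 1)`, which can never return 0;
the alternative "exceeds the null 95th percentile" criterion is reported as
a boolean alongside. Shuffling operates on the pooled aggregate (trials of
all subjects together); a per-subject analysis is obtained by calling the
function on one subject's table.

**Numerical choices.** R² of a constant series is defined as 0 (SS_tot = 0
guard). Ties on the grid go to the lowest frequency. Frequencies that alias
the bin grid (e.g. 50 Hz on 20 ms bins, where the sine column vanishes) are
detected by QR rank and excluded from the maximizer; a single-frequency fit
at such an f raises a classed singular-fit error naming the frequency.
Internally the scan projects the centered series onto per-frequency
orthonormalized sine/cosine pairs, which is numerically identical to
per-frequency OLS (tested to 1e-12) but lets thousands of permutations be
scanned as two matrix products.

**Group consistency.** Per subject, the 0/1 outcomes are regressed on
`[1, sin(2πfd), cos(2πfd)]` (a linear probability model, matching the
field's least-squares usage; no logit link by design). The per-subject
(β_sin, β_cos) pairs are tested against zero with Hotelling's T²;
`F = T²(n−2)/(2(n−1))` against `F(2, n−2)`.

# FIR deconvolution and delay statistics

Preprocessing drops the first 6 TRs, subtracts the OLS linear trend, and
normalizes to the mean of the retained raw series (×100 → percent signal
change); event TR indices shift by −6. The FIR design assigns each event to
the TR containing the keypress (the package's primary convention; aligning
to the visual stimulus instead is a config switch) and gives each event type
7 indicator columns for lags 0–6. Indicators are *not* summed on overlap:
events are ≥15 s apart by design, so an overlapping (type, lag) cell marks a
degenerate input and is flagged with a warning instead. Runs are
concatenated after preprocessing and share a single constant.

The module's core oracle is exactness: on noiseless, full-rank synthetic
data the OLS betas equal the injected lag curves to machine precision, and
residuals are orthogonal to every design column. The "integral from 3 to
12 s divided by time" summary is discretized as the arithmetic mean of the
lag-1..4 betas (rectangle rule at TR = 3 s); a trapezoid option exists.
Paired delay contrasts are one-tailed in the direction peak > trough
(150 > 70, 150 > 230, 310 > 230, 310 > 70) with Holm step-down adjustment;
the repeated-measures ANOVA reports partial η² (the variant is labelled,
since "η²" alone is ambiguous). Event-timing homogeneity within the TR is
checked with the Rayleigh test, `z = nR̄²`,
`p = exp(−z)(1 + (2z − z²)/(4n))`; the approximation is accurate for n ≥ 5
(smaller inputs are accepted because degenerate cases like two antipodal
phases are still well defined).

# Residual connectivity

Epochs collect the V1 and M1 residuals at TR offsets −1..4 relative to the
event TR (−3 to +12 s). One reading ambiguity is acknowledged: a "−3 to
12 s" window could be indexed in more than one way around the event TR; the
offset set {−1..4} is the reading implemented, and it is a parameter.
Correlations are computed **across events at a fixed offset** (matching the
per-TR display of the difference time course); a concatenated-samples
variant exists behind a flag for sensitivity analysis. The six offset r's
are averaged without Fisher-z by default (a z-averaging option exists).
Zero-variance vectors yield r = 0 with a warning rather than dropping the
delay. The bootstrap resamples events with replacement within each delay —
the aggregate-observer unit — and reports the one-tailed add-one p for
mean_r(peak) − mean_r(trough) ≤ 0.

# The forward model

Three inputs on a 10 ms grid over [−5, +25] s around action onset:

* **ramp** (readiness potential): rises linearly 0 → a_ramp over
  [−2, −0.55] s and returns to baseline afterwards. The "completed by
  −550 ms" wording is read as back-to-baseline; a plateau variant is a flag.
* **negative boxcar** (oscillatory suppression): a_box ≤ 0 on [−0.55, +4] s.
* **visual delta**: a unit-integral impulse of weight g·a_vis at the
  visuo-motor delay. The gain g multiplies *only* the delta — the stated
  mechanism is visual response gain, never motor components.

Each input is convolved with the gamma-family kernel
`h(t) = ((t−δ)/τ)^{n−1} e^{−(t−δ)/τ} / (τ(n−1)!)` for t > δ (zero
otherwise), τ = 2 s, order 3, δ = 3 s, renormalized to unit area on the
grid so amplitudes keep the percent-BOLD scale. The exact functional form is
a package choice (the literature's "standard" kernel family); the onset
delay is a pure shift, giving a peak at δ + (n−1)τ = 7 s. Sampled inputs
with jump discontinuities (ramp end, boxcar edges) get half-weighted edge
samples before convolution — a trapezoid quadrature that makes TR samples
converge at O(dt²), so halving the 10 ms step moves them by < 1e-4.

Amplitude fitting is linear least squares on the convolved unit-amplitude
component curves at the TR samples. g and a_vis cannot both be free (only
their product is identified); when g is free, a_vis is held and g is solved
linearly on the a_vis-scaled delta regressor. `estimate_visual_gain()` fits
(a_ramp, a_box, a_vis) on the trough curve, then g alone on the peak curve,
with no positivity clamp (suppression g < 1 is reported as estimated).
Defaults: a_ramp = 0.27 and g_peak = 1.33 are the reported fitted values for
this paradigm; a_box = −0.2 and a_vis = 10 are not published anywhere and
were chosen once so the simulated vision-only response peaks near 1.3 %BOLD
with qualitatively correct curve shapes.

# What the generator emulates — and what it does not

Behavioral trials: delays uniform on 0–600 ms in 10 ms steps (61 values),
Bernoulli outcomes with
`p(d) = baseline + amp·sin(2πf d/1000 + φ)`; defaults baseline 0.7,
amp 0.1, f 5.4 Hz. The oscillation amplitude on the probability scale is not
published; 0.1 is a testability choice. BOLD runs: 130 TRs of 3 s, events
every 19 s on average (SD 3 s, truncated-normal gaps floored at 15 s — the
instructed minimum inter-keypress interval — and never below 5 TRs), four
delay conditions (70/150/230/310 ms) with optional per-delay weights
mirroring the 17/17/13/13 trial-count asymmetry, no event in the last 7 TRs.
Continuous gap accumulation leaves the onset phase within the TR
approximately uniform, which the Rayleigh check verifies.

Each run's series is: sum of per-event forward-model lag curves (V1 gets the
delta with the delay-dependent visual gain, default 1.33 at 150/310 ms; M1
only ramp + boxcar) + linear drift + independent white noise + a shared
noise source added identically to both ROIs, multiplied within −3..+12 s
around each event by a per-delay gain. The event-gated shared gain is the
simplest mechanism producing delay-dependent residual connectivity, with a
closed-form target `r = s²g²/(s²g² + σ²)` used by the recovery tests. The
generator composes everything on the percent-BOLD scale; `baseline_bold >
0` wraps it as scanner-like raw data for pipelines exercising the
preprocessing. Not emulated: volumetric/NIfTI data, physiological
(cardiac/respiratory) noise, motion, eye movements, nonstationary drifts
beyond linear. A green test therefore establishes statistical correctness
of the estimators on the stated world, not robustness to artifacts real
data contain.

# Acceptance worlds and a known power limitation

The acceptance suite fixes its own worlds: the aggregate behavioral world
(7,000 trials ≈ 7 subjects × ~1,000) must recover 5.4 Hz within ±0.3 Hz
with permutation p < 0.05 in ≥90% of seeds; the null world (amp = 0) must
reject at ~5%; noiseless worlds must be recovered exactly.

For the connectivity world the suite uses shared_sd = 0.5 and
noise_sd = 0.15 (shared-to-independent variance ratio ≈ 11), chosen by a
pre-hoc power analysis rather than realism: with 160 events, 6 offsets and
a 20% gain contrast, the z-value of the peak−trough difference saturates
near 2.7 as the shared fraction grows, and the full pipeline (FIR
residualization, finite-sample bootstrap SEs at ~40 events/delay) lands
near z ≈ 2.0 — per-seed power ≈ 0.65 with a hard ceiling ≈ 0.86 at the
statistic level. The ≥80%-of-seeds detection criterion at this event count
is therefore beyond the design's detectability ceiling for *any* noise
setting, and the corresponding assertion fails honestly rather than being
loosened; roughly double the events (or a ~35% gain contrast) would be
needed. The implied residual correlations (~0.92) are higher than real
aggregate data (~0.5); at realistic ratios the same test has power ≈ 0.64
per seed. The null-calibration half of that criterion passes.

# Known limitations

* Linear probability model for single-trial outcomes (by design, matching
  the field's usage); no binomial GLM link.
* The permutation scan holds the bin membership fixed (delays are not
  shuffled), which is exactly the stated surrogate scheme but means empty
  bins never vary across surrogates.
* The connectivity bootstrap resamples events, not subjects; a per-subject
  repeated-measures route is available only as paired t tests on per-subject
  correlations computed by the caller.
* `hrf_kernel`'s grid renormalization assumes the grid covers the kernel
  support (~δ + 10τ); short grids inflate the tail mass.
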