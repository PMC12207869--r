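---
title: "Quantifying rest-phase torpor responses from skin-temperature telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rest-phase torpor responses from skin-temperature telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small wintering passerines face a trade-off between starvation and predation:
anti-predator behaviour costs foraging intake, and nocturnal torpor — a
reversible drop in metabolic rate and body temperature — can repay that
energy debt. A field test of this idea manipulates *perceived* predation risk
during the daytime active phase (conspecific alarm-call playback in
alternating 5-day blocks, with the two study sites on opposing sequences)
and measures the birds' nocturnal thermal response with temperature-sensitive
radio transmitters glued to the skin. A receiver-logger near each roost
records every transmitter's pulse interval at 10-min intervals; pulse
interval is a monotone function of transmitter temperature, so a
bench-fitted cubic calibration converts it to skin temperature
(T~s~), a standard proxy for core body temperature in birds this small.

`torportel` implements the full analysis chain for such an experiment:

1. **calibration** — per-transmitter cubic fits and pulse-to-temperature
   conversion;
2. **ingest/segmentation** — grid regularisation, circadian phase windows,
   bird-night assembly, gap and carry-over exclusions;
3. **torpor metrics** — individual normothermic baselines, torpor
   thresholds, nightly depth and duration;
4. **covariates** — air temperature and wind on the study's exact averaging
   windows;
5. **mixed models** — the three REML linear mixed models with backward
   simplification, variance-partition R², and parametric-bootstrap
   prediction intervals;
6. **synthetic data** — a generator planting known parameters, so the whole
   pipeline is validated by parameter recovery.

## Analysis definitions

Local clock time partitions each day: the **rest phase** runs 17:00–08:00
(spanning midnight, 90 grid slots at 10 min), the **active phase**
07:00–17:00, and daily medians use 08:00–17:00. The stated windows overlap
during 07:00–08:00; we resolve this by letting nightly metrics own
17:00–08:00, daily medians 08:00–17:00, and the *lowest daily active
reading* — the ingredient of the baseline — the full active phase
07:00–17:00. All windows are half-open `[start, end)`, so a 17:00 sample is
rest-phase, never active-phase. Both bounds are configurable via
`phase_windows()`.

A **bird-night** is one evening's rest window and carries the condition of
the *preceding daytime*, because the playback is an active-phase exposure
whose response is expected the following night. Nights missing more than
3 h of the 90-slot window are excluded (`gap_gt_3h`); the first 2 days of
any control block that follows a treatment block are excluded
(`carryover_day`) to limit lingering responses, while a leading control
block is untouched.

Each bird's **normothermic baseline** is the mean over its qualifying
control days of the lowest active-phase reading; days qualify when included
(non-carry-over) and backed by at least 21 active-phase observations,
mirroring the "> 20 points" median rule. The **torpor threshold** is
exactly 5 °C below the baseline. Nightly **torpor duration** is the sampled
time *strictly* below the threshold (a tie at the threshold is
normothermic — ties have probability zero in real data but the rule must be
deterministic), counting all sub-threshold time whether or not contiguous;
missing samples contribute nothing (no interpolation across gaps — nights
with large gaps are already excluded, and this choice is conservative).
`torpor_bouts()` exposes contiguous-run segmentation, but total time below
threshold is the quantity modelled.

## The mixed models

Three REML models, fitted with `lme4`/`lmerTest`:

| response | air-temperature covariate | random structure |
|---|---|---|
| daily median active T~s~ | active-phase mean (07:00–17:00) | intercept per bird |
| nightly minimum T~s~ | 24-h mean (07:00 → 07:00) | intercept + treatment slope |
| nightly torpor duration | 24-h mean | intercept + treatment slope |

All start from the fixed-effect menu {treatment, T~a~, daily maximum wind of
the preceding daytime, body mass at capture, sex}, with control as the
reference level so the treatment coefficient reads "treatment minus
control". "Sequential removal of least-significant terms" is operationalised
as backward elimination of the largest-p term at α = 0.05 with the
treatment term protected — protection is required because the daytime model
retains a clearly non-significant treatment term in the study this design
follows, so simplification evidently never removed it.

P-values default to Satterthwaite degrees of freedom. We chose this over a
single residual-df approximation because reported mixed-model tables of
this kind print *different* df for different coefficients of one model,
which is the signature of Satterthwaite; `df_method = "residual"` is
available, and rows where a boundary (singular) fit leaves Satterthwaite df
undefined fall back to residual df so that simplification always has a
p-value. A random-slope model that fails to converge — a real possibility
with 16 individuals — is refitted with a random intercept only and loudly
flagged (`fallback = TRUE`), never silently.

Marginal and conditional R² are variance partitions: fixed-effect variance
(variance of the fixed linear predictor) over fixed + random + residual,
with the random-effect variance computed as the mean per-observation
quadratic form of the random-effect design with the fitted covariance, so
random slopes are handled. Prediction intervals use a parametric bootstrap
(simulate from the fitted model, refit, predict at reference covariates:
each condition, continuous covariates at their means), percentile 95%
intervals, deterministic given a seed; the study-scale default is 1000
replicates, tests use fewer.

## What the generator plants, and how

`scenario_config()` defaults *are* the study conditions: 2 sites × 8 birds
(6 F / 10 M), 15 days in opposing 5-day blocks, 10-min sampling, winter air
temperature (daily minima 2.5 ± 3.1 °C near 06:00, maxima 17.2 ± 2.4 °C
near 14:00, interpolated by half-cosines plus small AR(1) noise), daily
maximum wind 32.2 ± 15.5 km/h floored at 11 km/h, sensor noise 0.3 °C, and
out-of-range gap probabilities of 25% by day and 2% by night. The daily
min/max SDs and the AR(1) noise parameters are generator choices taken from
the observed weather ranges.

Per bird, the active plateau is `N(39.6, 1.0)` and the resting normothermic
level is the plateau minus a truncated-normal gap (≥ 1 °C) whose moments are
chosen so the resting level has exactly mean 37.3 and SD 1.2 °C. Per
bird-night, the planted nightly minimum is
`N(30.0 − 1.25·treatment + 0.15·(Ta₂₄ − T̄a), 1.5)` truncated at the resting
level, and the planted duration is
`N(3.8 + 2.1·treatment − 0.15·(Ta₂₄ − T̄a), 2.3)` censored to [0, 12] h
(censoring beyond 12 h is flagged). T̄a is the scenario's grand-mean air
temperature. The planted treatment effects (−1.25 °C, +2.1 h) sit between
raw condition differences and model-adjusted contrasts of the motivating
field data, so a balanced design recovers both descriptive and model-based
targets; the night-model T~a~ slopes are generator choices (the motivating
study does not print them), with signs matching its figures.

The two nightly draws are independent, so a small fraction of nights is
physically contradictory (a positive duration with a minimum at or above
the threshold, or the reverse). We reconcile by reflecting the minimum
about the threshold for exactly those nights. Reflection is mean-preserving
to first order — the Monte-Carlo tests confirm the configured condition
means survive to within a few hundredths — whereas re-drawing from a
truncated distribution would shift the planted control mean by roughly a
quarter of a degree.

### Trace shape

No published trace equations exist for this kind of record, so the shapes
are package design, chosen to make the construction identities *measurable*
under sensor noise rather than merely true of the noiseless curve:

* morning rewarming 07:00→08:00 is a quarter-sine from the resting level to
  the plateau, steep at 07:00 so the resting-level anchor sample has a
  single noisy competitor (a flat-started arc would bias the baseline
  estimator low);
* evening cooling and pre-dawn rewarming are quarter-cosine/-sine arcs
  meeting the torpor threshold with non-zero slope;
* the torpor bout interior is piecewise linear with brief (6-min) steep
  drops just inside each threshold crossing and just above the minimum.
  Fast crossings matter: if the trace drifted slowly near the threshold,
  symmetric sensor noise would remove more sub-threshold time than it adds
  (the trace lingers longer inside the bout than outside at the same
  distance from the threshold) and nightly duration would be biased low by
  ~0.4 h. The terminal plunge leaves at most one sample near the minimum,
  so the observed nightly minimum tracks the planted one instead of being a
  noise order statistic.

The bout is placed so arousal completes near 06:00 and the trough bottom
falls on a grid point; on noiseless data the nightly minimum equals the
planted minimum exactly and the measured duration equals the planted one
within one sample interval (0.167 h). Generated temperatures are clamped to
a 15–45 °C physiological guard band.

The emitted bundle encodes observations the way a receiver logger would:
each transmitter has a true strictly-decreasing cubic response
(~600–1400 ms over roughly −1 to 51 °C, randomly perturbed per
transmitter, inverted by dense monotone interpolation), bench calibration
points at 5–45 °C carry 0.02 ms pulse noise, and logged pulses carry
0.02 ms timing jitter, so re-reading a bundle reproduces the in-memory
series to better than 0.01 °C while still exercising a genuine calibration
fit (R² ≈ 1, comfortably above the 0.99 quality gate).

### What the generator does not emulate

Missingness is independent per sample with a higher daytime rate; the real
mechanism (birds foraging out of receiver range, transmitter battery
failure on final nights) produces *runs* of missing samples, which interact
with the >3 h rule differently. Day-to-day within-bird variation beyond the
air-temperature effect is not planted, so conditional R² of the daytime
model is far higher on synthetic data than in any field dataset. There is
no behavioural response model — treatment effects are planted directly on
the night-level quantities, not mediated through foraging. Passing the
recovery suite therefore demonstrates that the *pipeline* is faithful
(exclusion rules, thresholds, windows, estimators, models), not that the
generator is a realistic bird.

## Numerical and degenerate-input choices

Calibration cubics are fitted on a centred/scaled pulse variable and
expanded back to raw-millisecond coefficients (raw powers reach 10⁹ and
cost ~8 digits); fits must be strictly monotone over the calibrated range
(checked on a dense grid) and pulses outside the range plus a 5% margin
become missing rather than extrapolated — cubic extrapolation is unbounded
and one bad pulse could fabricate a torpor bout. Duplicate
(bird, timestamp) logger rows collapse to their median. A bird with no
qualifying control day is unusable for night metrics and is dropped with a
logged reason; an empty condition in the descriptive summary warns rather
than errors. Weather windows require 90% grid coverage (the motivating
study had a dedicated on-site logger; this guard is for other data
sources).

## Problem sizes used in validation

The recovery suite runs 20 replicate scenarios at the full study size
(16 birds × 15 days, ≈ 35,000 samples per replicate) for the acceptance
quantities; unit tests use 10-day or noiseless variants of the same
scenario, and Monte-Carlo checks of planted distributions use 15–20
replicates. These sizes give Monte-Carlo standard errors an order of
magnitude below the acceptance tolerances.

## Known limitations

* The duration estimator counts sampled time only; with 10-min sampling a
  bout shorter than one interval can be missed entirely.
* The baseline estimator uses a noisy daily minimum and is slightly biased
  low (order 0.05 °C at the default noise level); the induced threshold
  error propagates into duration at about 2/slope h per °C.
* Satterthwaite p-values on boundary fits fall back to residual df; with
  16 individuals, between-bird terms (mass, sex) have few effective df and
  their retention frequency under the null is correspondingly noisy.
* The carry-over rule assumes block structure; irregular schedules are
  handled (any control run following a treatment run) but untested against
  field practice.
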