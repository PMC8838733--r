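---
title: "Estimating running kinetics from a single sacral accelerometer: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating running kinetics from a single sacral accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peak vertical ground reaction force (Fz,max), contact time (tc), and flight
time (tf) are core descriptors of running mechanics. The reference
instrument is a force plate, which is neither portable nor cheap. A single
accelerometer strapped to the sacrum — close to the body's centre of mass —
offers a field-usable surrogate: by Newton's second law, the vertical
component of the measured proper acceleration, multiplied by body mass,
approximates the vertical ground reaction force, from which all three
variables follow.

`imugait` implements both measurement chains and the statistics needed to
compare them:

* **GSM** (gold standard): vertical plate force, low-pass filtered at 20 Hz
  with a 4th-order zero-phase Butterworth, foot-strike (FS) and toe-off (TO)
  detected where the force crosses 20 N upward and downward.
* **IMUM** (IMU method): estimate the sensor tilt from the gravity
  direction (each axis truncated-Fourier filtered to 0.5 Hz, per-axis
  medians, minimal rotation onto the laboratory vertical), reorient,
  truncate the vertical axis to 5 Hz, convert to force
  (`fz = az * g0 * body_mass`), then detect events with the same 20 N
  threshold.

Per stride (FS to next FS of the pooled event stream — a single sacral
sensor cannot lateralize feet, so one "stride" here is one step cycle):
`tc = TO - FS`, `tf = nextFS - TO`, and `Fz,max` is the stance maximum in
body weights. Trials are summarized as means over the first 10 strides
after the 30 s mark, and the two methods are compared with Bland–Altman
bias and limits of agreement (`bias ± 1.96 σ_diff`, i.e. bias ± the
smallest real difference), absolute and relative RMSE, a proportional-bias
regression, and Cohen's *d*.

## The truncated Fourier filter

"Truncation to *X* Hz" is implemented literally: a full-window DFT, every
bin with |f| > X zeroed (the bin exactly at the cutoff is kept by default;
`keep_cutoff_bin = FALSE` drops it), inverse DFT, real part. The filter is
linear, idempotent, and exactly DC-preserving. No taper or padding is
applied: trials are analyzed in their interior (strides after 30 s in a
~41 s record), far from the window edges where ringing from non-bin-aligned
components concentrates. For the nominal step rate of ~2.5 Hz a 5 Hz
truncation keeps only the DC component and two harmonics of the stance
waveform, which is the point of the method: it suppresses impact transients
and soft-tissue oscillation, at the price of a systematic stance-shape
deformation discussed below.

## Tilt estimation and reorientation

A worn sensor is never perfectly aligned with the laboratory vertical. The
0.5 Hz truncation isolates the quasi-static (gravity) component of each raw
axis; the per-axis medians form the gravity direction in the sensor frame;
and the package builds the *minimal* rotation (axis = ĝ × ẑ, angle =
arccos ĝ·ẑ, Rodrigues form) mapping that direction onto [0, 0, 1]. A
single tilt angle would only be unambiguous for a planar tilt; the full
rotation generalizes it without extra assumptions. Two degenerate cases are
handled explicitly: an exactly upside-down sensor (angle π) rotates about
the laboratory x-axis, and a gravity estimate shorter than 0.1 g (a sensor
in sustained free fall, or a gap) is refused as "no gravity reference".

Because the minimal rotation M(u) mapping u onto ẑ satisfies M(u)ᵀẑ = u,
the reoriented vertical channel equals ĝᵀa regardless of how the sensor
was tilted — so the IMU pipeline's outputs are tilt-invariant by
construction, which the test suite verifies to 10⁻⁶ on clean trials.

## Event detection and its numerical choices

Crossings of the 20 N threshold are refined by linear interpolation between
the bracketing samples, reducing the ±2.5 ms quantization of a 200 Hz
record to microseconds on smooth signals (`interpolate = FALSE` falls back
to the bracketing midpoint). Stances shorter than 25 ms and flights shorter
than 10 ms are treated as threshold chatter — both values sit far below
physiological minima, so they never clip true events. An incomplete leading
stance and incomplete trailing phases are discarded.

The plate filter is applied zero-phase (forward–backward), with the
order-compensated design standard in motion analysis: each pass uses an
order/2 filter and the design cutoff is raised by Winter's dual-pass factor
`(√2 − 1)^(−1/(2·(order/2)))` ≈ 1.247 so the −3 dB point of the combined
response sits at the requested 20 Hz. A single-pass mode exists but delays
every event by a speed-dependent group lag.

**A deliberate limitation to know about.** The simulator's stance is a
half-sine with a derivative discontinuity at FS and TO. Any ~20 Hz low-pass
reads ~40 N at that corner and therefore shifts each 20 N crossing a few
milliseconds outward; with the adopted design the simulated gold standard
widens tc by ≈ +6.5 ms against the continuous-time 0 N-crossing ground
truth (≈ +9.5 ms without the cutoff correction — we verified the numbers
against an independent filtering implementation). This is a property of the
idealized stance shape, not of the detector: each individual event is still
within one plate sample of truth, and real plate forces rise smoothly from
zero, where the effect is smaller. Tests therefore hold the gold standard
to a two-sample (10 ms) recovery bound on tc/tf and to 0.01 BW on Fz,max.

## What the 5 Hz truncation does to the estimates

With step frequency f₀ = 1/(tc + tf) ≈ 2.5 Hz, truncating to 5 Hz keeps
only DC, f₀, and 2f₀. The reconstructed "force" is a smooth two-harmonic
wave whose 20 N crossings sit well outside the true stance: for the default
configuration (tc = 0.28 s, tf = 0.12 s, Fz,max = 2.5 BW) the deformed
contact time is 322.6 ms (+42.6 ms) and the deformed peak 2.579 BW
(+0.079 BW). The package does not hide this: it is the method's intrinsic
bias, and the validation machinery exists to quantify it. The expected
deformation is computed independently in the test suite by a
periodic-waveform oracle (2¹⁶-point DFT of one exact gait cycle, bins above
5 Hz zeroed, crossings re-solved), and the full pipeline reproduces the
oracle to 0.3 ms. On real running signals — with richer spectra, impact
content, and soft-tissue dynamics — the deformation is smaller; published
sacral-IMU biases of this kind are on the order of 10–20 ms. Synthetic
results here characterize the pipeline's correctness, not the method's
field accuracy.

Because both methods use the *same* toe-off events inside a common stride
span, the error that tc gains, tf loses: the tf bias is the negative of the
tc bias and the two RMSEs agree, which the acceptance suite checks to 2 ms
on a 90-trial noisy cohort.

## The simulator: what it emulates, and what it does not

`generate_trial()` emulates the acquisition setup of a treadmill validation
study: a 200 Hz force channel and a 208 Hz, ±8 g accelerometer with a
constant inter-device clock offset of at most ±50 ms (durations are
offset-invariant, so agreement statistics are unaffected — exactly why such
a study tolerates loose synchronization).

* **Stance force**: half-sine `F(t) = Fz,max·m·g0·sin(πt/tc)` — the
  spring-mass "active peak" with no separate impact peak in the force
  channel. A `balance` mode sets `Fz,max = π(tc+tf)/(2tc)` per cycle so the
  cycle-averaged force equals body weight (the half-sine does not balance
  impulse for arbitrary parameter triples).
* **Accelerometer**: proper acceleration — F/(m·g0) in g during stance,
  0 g (free fall) in flight; a damped foot-strike transient
  `A·e^(−t/20 ms)·sin(2π·25 Hz·t)` injected on the laboratory vertical
  (a physically vertical impact, which is why tilt invariance is exact);
  a small 0.05 g anterior–posterior sway sinusoid (a documented free
  choice, not a modeled quantity); rotation by the sensor tilt; white
  sensor noise per axis; clipping at ±8 g.
* **Cycle-to-cycle variability**: multiplicative, mean-preserving lognormal
  jitter on tc and tf with CV 0.02 — a typical treadmill stride-time
  variability.
* **Cohorts**: per-participant parameters drawn from per-speed normal
  distributions (defaults loosely emulating published group values at 9,
  11, 13 km/h, e.g. tc 278 ± 22 ms at 9 km/h), with latent z-scores shared
  across speeds so individuals keep their rank ordering, as in a
  repeated-measures design. Draws are truncated to running gaits
  (tf ≥ 40 ms, tc ≥ 150 ms, mass 45–100 kg).

Not emulated: multi-segment and soft-tissue wobble dynamics, overground or
graded running, clock drift (the offset is constant), gyroscope and
magnetometer channels, and the rich harmonic content of real sacral
acceleration. Consequently, passing tests demonstrate the pipeline computes
the method correctly and that the protocol's structural properties hold;
they do not certify field accuracy on real runners.

One consequence of the independent tc/tf draws is occasional marginal
gaits (duty factor near the walking boundary) whose 5 Hz reconstruction
never crosses 20 N, or merges two stances. The comparison protocol is
premised on both methods measuring the *same* strides, so `run_cohort()`
excludes a pair — with a warning — when the two methods' mean stride
durations disagree by more than 25% (matched recordings differ by well
under 5%; merged ones by 60–100%). On a 90-trial cohort this typically
excludes 0–3 pairs.

## Statistics conventions

Differences are `est − gold`, so positive bias means the IMU method
overestimates. The SD of differences uses the n−1 denominator. Limits of
agreement are `bias ± 1.96·σ` (the 1.96 written literally, as the smallest
real difference is defined); their confidence intervals use the standard
approximation `SE(LoA) = σ·√(3/n)`; the bias CI uses the t distribution.
The proportional-bias regression uses the pairwise mean `(est+gold)/2` as
abscissa by default (the Bland–Altman plot convention; regressing on the
gold value alone is available). Cohen's *d* is `(mean gold − mean est)`
over the pooled SD — negative when the IMU method overestimates — with a
paired variant available; magnitude labels (very small/small/moderate/
large) attach at the midpoints (0.105, 0.35, 0.65) of the conventional
anchor values 0.01, 0.2, 0.5, 0.8. Relative RMSE is normalized by the mean
gold-standard value of the group being reported.

## Problem sizes and reproducibility

Every stochastic element — stride jitter, sensor noise, cohort draws,
per-trial tilt and offset — descends from a single integer seed, and
regenerating with the same seed reproduces traces byte-for-byte. The
package's own validation uses 30-participant × 3-speed cohorts (~41 s
trials, ~8,500 accelerometer samples each), which run the full
simulate → GSM → IMUM → agreement chain in seconds; the deterministic
statistics are exercised against closed forms and brute-force oracles
(explicit trigonometric Fourier reconstruction, analytic crossing times,
OLS in closed form) at tolerances of 10⁻⁸–10⁻¹⁰.
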