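---
title: "Closed-loop ripple detection and extinction metrics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop ripple detection and extinction metrics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swrloop)
```

swrloop simulates and analyses the computational core of a closed-loop
experiment in which hippocampal sharp-wave ripples (SWRs) — transient
150–250 Hz oscillations riding on a sharp-wave deflection during non-REM
(NREM) sleep — trigger electrical stimulation within tens of milliseconds of
their onset. The package covers five connected pieces: a ground-truthed LFP
simulator, the causal online detector that would run on acquisition
hardware, a zero-phase offline detector used as the post hoc reference, the
scoring of online triggers against reference events, and the behavioural
metrics used to quantify fear extinction.

## The synthetic recording model

A session is two channels of Gaussian $1/f^{\alpha}$ background noise
(default $\alpha = 1$, broadband SD 50 µV) sampled at 500 Hz (or 20 kHz for
the raw-acquisition path): a *ripple channel*, standing for a CA1
pyramidal-layer electrode, and a *noise channel*, standing for a
neocortical reference site with no ripple activity. Sleep states follow an
alternating-renewal process — exponential dwell times with per-state means,
chained by a fixed embedded transition matrix — and scale the background SD
per state (NREM 1.0, REM 0.8, WAKE 1.2), so state transitions perturb any
fixed detection threshold the way they would in a real recording.

Ripples occur at Poisson times within NREM epochs only, with a refractory
minimum gap of 0.35 s (so that no true event falls inside the detector's
lockout shadow of its predecessor). Each event is a Hanning-windowed
sinusoid (carrier drawn uniformly from 160–230 Hz) superimposed on a
negative raised-cosine sharp-wave deflection of the same extent. Durations
are log-normal (median 100 ms, clipped to 60–118 ms). Amplitudes are
expressed in units of the **baseline ripple-band RMS** — the SD of the
causally band-pass-filtered, ripple-free background over the first two
minutes — which makes them directly commensurable with `mean + k·SD`
threshold calibration: an `amplitude_z = 5` event peaks at five baseline
SDs in the ripple band. The amplitude distribution is log-normal with
median 5 and 10 % of events below 3, right-censored at 8 SD; the ceiling
mimics the bounded dynamic range of a real amplifier chain and, just as
importantly, keeps the fourth moment of the power trace finite enough that
z-scored power thresholds (below) retain their meaning. Brief broadband
artifact transients (8 ms Hanning-windowed white noise at 8 baseline SDs,
0.05/s) are added to **both** channels, giving the noise-channel veto
something real to do.

The version-pinned evaluation fixture (`benchmark_config()`) is a
30-minute, NREM-dominated sleep session (dwell means NREM 900 s, REM 60 s,
WAKE 30 s, starting in NREM) with the event statistics above, run at seeds
1–10. These parameters were calibrated once, when the package was designed,
so that the complete simulator–detector–scoring chain operates in the
regime reported for real closed-loop recordings (positive detection above
80 %, false positives below 8 %, trigger latencies of 15–27 ms), and are
fixed in version control; the acceptance script recomputes the rates from
scratch on every run.

What the generator deliberately does **not** model: spiking, theta/gamma
rhythms and other structured oscillations of wake and REM, electrode drift,
movement artifacts with channel-specific shapes, and any biophysics of the
stimulation itself. Passing tests on this synthetic benchmark therefore
demonstrate that the detection and scoring machinery is correct and
operates in the published regime — not that the specific rate numbers would
transfer to any particular animal.

## The online (closed-loop) detector

The streaming path mirrors what embedded detection hardware does:

1. **Causal band-pass.** A 4-pole Butterworth filter applied as a
   forward-only recursion; 150–250 Hz on the ripple channel, 80–500 Hz on
   the noise channel. At the 500 Hz online rate the upper edges sit at or
   above Nyquist, so they are clamped to 0.95 × Nyquist (237.5 Hz): a filter
   edge at Nyquist is ill-defined, and real acquisition chains band-limit
   before decimation anyway. The filter's group delay is a genuine part of
   the closed-loop latency.
2. **Trailing RMS.** A 10 ms sliding root-mean-square, using only past
   samples. Short enough to keep latency in the tens of milliseconds, long
   enough to smooth single-cycle fluctuations.
3. **Thresholds.** `calibrate_thresholds()` sets each channel's threshold
   at `mean + k·SD` of its RMS trace over a 60 s baseline (default
   `k = 4` on both channels), emulating the per-animal threshold adjustment
   done before an experiment. When state labels are available the baseline
   is the first 60 s of the first NREM epoch at least that long — the
   automated equivalent of an experimenter choosing a quiet sleep baseline.
   Calibrating blindly on the first minute of the recording misbehaves
   whenever that minute happens to fall in REM or wake, whose different
   background power scales the threshold by up to ±20 %.
4. **Trigger state machine.** At each rising edge of the ripple RMS above
   threshold, exactly one log entry is emitted: `VETOED` if the noise-channel
   RMS is concurrently above its own threshold (the veto is evaluated at the
   crossing sample itself — the simplest causal reading of requiring the
   absence of a noise signal, and it takes precedence over the lockout when
   both apply), `LOCKED_OUT` if a trigger fired less than 250 ms before
   (covering the 100 ms stimulation train plus artifact settle), otherwise
   `FIRED`. Triggers are stamped `crossing + processing_latency` (default
   10 ms, the assumed detection-to-stimulation chain delay).

Processing is chunked with carried filter, RMS and state-machine state, so
results are exactly independent of chunk size, and truncating the input
never changes triggers emitted before the truncation point — the defining
property of a causal detector, asserted directly in the tests by comparing
against a whole-vector batch replica.

Stimulation protocols are data: the rewarding medial-forebrain-bundle train
(fourteen 1 ms, 100 µA pulses at 140 Hz — onsets spanning 13/140 s, nominal
train length 100 ms) and the ripple-disrupting single 0.5 ms commissural
pulse (5–15 V). `render_stimulus_artifact()` adds a saturating square
transient on both channels during each pulse so the offline path can be
exercised under realistic contamination.

## The offline (post hoc) detector

The reference detector runs on the full recording with no causality
constraint: decimate to 500 Hz if needed (multistage zero-phase Butterworth
anti-aliasing, stages of at most factor 10; a single-stage IIR at a
normalised cutoff of 0.02 is numerically fragile and a Chebyshev design
would not even pass a constant unchanged), zero-phase band-pass in the
ripple band, square, smooth, z-score, then extract events where the
normalized power exceeds **3 SD** at the peak with boundaries walked
outward to the nearest samples below **2 SD** (at most 150 ms from the
peak), merge overlapping candidates, and keep events whose duration lies in
**20–200 ms** (inclusive; durations are counted in integer samples so the
bounds are exact). When stimulation trains are provided, samples within
10 ms of any pulse are blanked: excluded from the z-scoring moments (the
artifact would otherwise inflate the SD) and unable to belong to events — a
deterministic replacement for manual artifact rejection.

Two numerical choices deserve emphasis:

* **Power smoothing.** The squared band-pass signal at 500 Hz oscillates
  through zero twice per carrier cycle, so on the raw squared trace a 2 SD
  boundary walk terminates within a couple of milliseconds and every event
  would fail the 20 ms duration floor. The squared signal is therefore
  smoothed with a centred **Gaussian kernel (SD 7 ms)** — roughly one
  ripple cycle — before z-scoring. The kernel shape matters: with a boxcar,
  every supra-threshold bump becomes a plateau of kernel width, so span is
  independent of bump height and the duration floor cannot separate brief
  transients from real events. With a Gaussian, span grows with the
  logarithm of peak height, which lets the same floor reject a constructed
  few-millisecond transient while accepting genuine ripples, and keeps
  onset/offset estimates of a strong 60 ms test event within 10 ms of
  ground truth.
* **Adaptive thresholds and event-free input.** Because thresholds are
  z-scores of the recording's own power trace, a recording with no events
  still surfaces its largest fluctuations as candidates; with the smoothed
  estimator some of these exceed the duration floor. The unsmoothed
  estimator (`offline_config(smooth_sd_s = 0)`) is maximally specific on
  event-free noise (its false-event rate on white noise is essentially
  zero, and the test suite asserts this below 0.05 events/s) but cannot
  localise event boundaries. The smoothed default trades that null
  specificity for boundary accuracy; its practically relevant
  false-positive behaviour — scoring against ripple-bearing recordings — is
  what the benchmark measures.

## Scoring online against offline

`match_triggers()` assigns each `FIRED` trigger to the unmatched reference
event whose window `[onset, offset + 50 ms]` contains the trigger time,
nearest onset first, ties toward the earlier event; the matching is
one-to-one. The post-offset tolerance exists because a trigger fires after
onset plus processing latency and may legitimately land just beyond the
reference offset. `detection_rates()` reports positive detections (PD),
false positives (FPD, unmatched triggers) and misses (MD, unmatched
events) as percentages of `n_pd + n_fpd + n_md` — the three-way partition
of the union of triggers and events, which is the convention under which
the three rates sum to exactly 100. `trigger_latencies()` reports
`trigger − onset` per matched pair in a 1 ms-bin histogram; with the default
configuration the latency budget decomposes into filter group delay
(~8–12 ms at ripple frequencies), RMS-window fill and threshold rise time,
and the 10 ms processing latency, which lands the modal bin in the
mid-twenties of milliseconds.

`sleep_architecture()` reduces a state sequence to time fractions per
state, the quantity compared between stimulated and unstimulated groups.

In `run_pipeline()`, accuracy is scored against offline events from the
*uncontaminated* recording: blanking removes precisely the events the
triggers responded to, so the contaminated event set cannot serve as the
reference (its size is still reported).

## Behavioural extinction metrics

Freezing arrives as percentages per tone (20 CS+ presentations per daily
extinction session, analysed in blocks of five). The metrics are
deliberately elementary and exactly reproduce the published procedure:

* `freezing_reduction(first_block, test)` = first-block freezing × 100 /
  post-training test CS+ freezing (may exceed 100);
* `remission_day()` — the first day whose reduction is **strictly** below
  20 %, censored at 7 days (sessions after remission are ignored, matching
  the experimental stop rule);
* `delta_freezing(probe, test)` — the signed difference in percentage
  points, e.g. remote-test minus post-training freezing.

The synthetic behaviour fixture draws per-animal post-training freezing
from a clipped normal (mean 75 %, SD 10, range 40–95), decays the
expected tone freezing exponentially across sessions (rate 0.36/session for
non-stimulated and open-loop animals — putting median remission near day
5–6 — and 0.72 for closed-loop), adds truncated-Gaussian per-tone noise
(SD 5 points), and adds fear-recovery increments at the renewal (+30),
remote (+25) and reinstatement (+20) probes for the NS and OL groups only.
These choices reproduce the qualitative group structure (closed-loop
animals remit in fewer sessions and show no fear recovery); the underlying
figure-level group medians of the original experiment are not printed
anywhere and are not reproduction targets.

## Problem sizes and determinism

Every generator takes an integer seed and is bitwise reproducible. The test
suite uses short sessions (1–5 minutes) for unit-level checks and the full
ten 30-minute benchmark seeds for the acceptance surface; the whole suite
runs in about a minute, the acceptance script in well under one. The
renewal-theory, Poisson-count, band-power, batch-equivalence and
closed-form decay oracles in the tests are implemented independently of the
package code paths they check (e.g. `stats::filter` recursions versus the
`signal` package's filters).

## Known limitations

* The background model is stationary Gaussian within each state; real LFP
  has non-stationary, heavy-tailed noise, so absolute false-positive rates
  on real data will differ from the benchmark's.
* The online/offline comparison shares the simulated ground truth only
  through the signal; nevertheless both detectors see the same synthetic
  waveform family, which flatters agreement relative to real recordings
  where event morphology varies.
* The veto is only as good as the noise channel's artifact share; the
  simulator's artifacts are perfectly shared across channels, the
  best case for the veto.
* Freezing trajectories are exponential in expectation; real extinction
  curves show day-to-day non-monotonicity that only enters here through
  per-tone noise.
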