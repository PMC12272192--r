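---
title: "Quantifying EEG amplitude suppression during neonatal breathing pauses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EEG amplitude suppression during neonatal breathing pauses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Apnoea — cessation of breathing — is near-universal in very preterm infants
and can depress cerebral oxygenation. Whether and how strongly cortical
activity is suppressed during apnoeas (inter-breath intervals of at least
15 s) and shorter breathing pauses (5–15 s), and how that suppression
relates to bradycardia, oxygen desaturation, event duration, age and sleep
state, is the question this package operationalises. It implements the
complete analysis chain for multimodal neonatal intensive-care recordings:
respiration (25 Hz), multichannel EEG (250 Hz, 10–20 subset referenced to
Cz), and monitor-derived heart rate and SpO₂ (1–5 Hz), together with a
synthetic generator of such recordings so that every stage can be validated
against known ground truth.

## Breathing pause identification

Respiration traces are high-pass filtered at 0.5 Hz (zero-phase
second-order Butterworth) and cleaned of amplitude outliers: samples beyond
5 standard deviations are linearly interpolated, iterated 10 times. Two
numerical choices depart from a naive reading of that recipe and are
deliberate:

* all zero-phase filters use odd-reflection padding, because unpadded
  forward–backward filtering produces edge transients whenever the signal
  does not start and end near zero;
* the outlier rule is additionally applied once *before* filtering. A
  zero-phase filter smears a single-sample artifact over its settling time
  (about 2 s at 0.5 Hz), leaving residuals of roughly 4 SD that no amount
  of post-filter interpolation can repair; excising spikes while they are
  still single samples makes the cleaning effective.

Breaths are upward crossings of an adaptive threshold equal to 0.5 times
the standard deviation of the signal spanning the previous 120 detected
breaths (the originally published impedance-pneumography algorithm used
0.4 × SD over 15 breaths; both are exposed as parameters). Before 120
breaths exist the SD is taken over all breaths so far, seeded by the first
60 s of signal. Crossings closer than 0.5 s are merged. Because the
threshold is proportional to the signal's SD, detection is exactly
invariant to amplitude scaling — a property the tests exercise directly.

Inter-breath intervals of 5–15 s become short breathing pauses and
intervals of at least 15 s become apnoeas. Only *isolated* events — no
other ≥5 s pause starting or ending within −60 s of the pause start to
+90 s of its end — enter the EEG analysis, so that single events are not
contaminated by periodic breathing. The window is anchored to the pause
extent (start for the backward edge, end for the forward edge), the
conservative reading of "relative to the pause".

For every event a *normal breathing* baseline is chosen in the 90 s before
onset: among windows of 30 s (apnoeas) or 10 s (short pauses) on a 1-s
grid, ending at least 15 s (respectively 5 s) before onset, the window
whose maximal overlapping inter-breath interval is smallest is selected,
ties going to the earliest window. Maxima are taken over intervals
*overlapping* the window, not only those fully inside it.

## The pause classifier

Shallow breathing and low-amplitude artifact produce spurious long
inter-breath intervals. Each candidate is therefore described by six
features — mean absolute value and SD of the thoracic trace, normalised by
the full-recording SD, in three windows: 10–1 s before onset, 1–10 s after
the pause end, and from 1 s after onset to 1 s before the end — and
screened by an unregularised logistic regression (threshold 0.5, with a
probability of exactly 0.5 conservatively labelled not-a-pause).
Performance is reported as balanced accuracy (mean of sensitivity and
specificity) under leave-one-infant-out cross-validation, so the evaluation
never sees the held-out infant's amplitude idiosyncrasies. The second
feature window is anchored to the pause *end*, making the pre- and
post-windows symmetric; the alternative (onset-anchored) reading of
"1–10 s after the pause" would overlap the pause interior for long events.

## Time-frequency EEG amplitude

EEG is band-pass filtered 0.1–30 Hz (zero-phase second-order Butterworth;
infant EEG carries little power above the gamma boundary), epoched from
−90 to +150 s around apnoea onsets and −90 to +90 s around short-pause
onsets, and screened channel-wise: any sample beyond ±500 µV rejects that
channel for that epoch. The amplitude screen is applied to all events
(visual screening of apnoea epochs is deliberately replaced by the same
automated rule, so the pipeline is fully reproducible).

The time-frequency amplitude (TFA) is computed by iterative narrowband
filtering: at centre frequencies 1.5, 2.5, …, 29.5 Hz the signal is
band-passed ±1 Hz, the analytic signal is formed via the FFT-based Hilbert
transform, and its modulus — the instantaneous amplitude — is
log₁₀-transformed (floored at 10⁻⁶ µV so silence stays finite). Statistical
segments are cut as ±15 s (apnoeas) or ±5 s (short pauses) around the pause
start and end; the matched baseline window (30 or 10 s, the same lengths)
is transformed identically and subtracted sample-wise, mapping the
baseline's samples one-to-one onto the event's time axis. A switch
(`baseline_average = TRUE`) subtracts the baseline's time-averaged spectrum
instead. Filter and Hilbert edge effects die out within about 2 s, so the
pipeline computes envelopes on segments padded by 5 s and discards the
padding; the stored envelope is decimated to 10 Hz (the ±1 Hz bands'
envelopes contain no structure faster than ~2 Hz), which changes no
statistic while keeping event stacks small.

## Vitals

Heart-rate samples outside 40–230 bpm and SpO₂ above 100% are marked
missing, never interpolated. The per-event change is the minimum over
−5 to +60 s relative to the pause end minus the *mean* over the baseline
window (the baseline statistic is a package choice; the extremum-based
event statistic argues against interpolating gaps). SpO₂ readings of
exactly 60% are flagged: bedside monitors truncate there, so large
desaturations are right-censored at −40 points and the associated model
slopes are, if anything, underestimated. Because the event statistic is a
windowed minimum, it is biased negative even under a flat series — the
tests quantify that bias against the order-statistic expectation.

## Group statistics

Event and baseline TFA segments are compared by sample-wise paired t-tests
across events (each pause paired with its own baseline; an infant-averaged
pairing is a switch), with Benjamini–Hochberg FDR control at q = 0.01
applied jointly over all time × frequency (× channel) samples of one map.
Samples where the paired differences have zero spread are assigned t = 0
(p = 1) when the mean difference is also zero. Both channel-wise maps and
channel-pooled maps (events averaged over channels first) are produced.

The per-event response for the association models is the change map
averaged over −5 to +5 s around the pause end, all 29 frequencies and all
retained channels. Five models relate it to heart-rate change, SpO₂
change, pause duration, post-menstrual age and sleep state — one covariate
per model, no correction across models — via

$$Y_n = \beta_0 + \beta_1 X_{n,1} + \gamma_1 Z_{n,1} + \varepsilon_n,$$

with per-infant random intercept and slope, fitted by REML (`lme4`).
Slope p-values use Satterthwaite degrees of freedom (`lmerTest`); the
result object records the method, and falls back to a normal approximation
when the Satterthwaite machinery fails on degenerate fits. Singular
random-effect covariances trigger a flagged refit with random intercept
only. Sleep state enters as a four-level factor (TA reference) with a
joint fixed-effect test. For post-menstrual age the response is first
averaged per infant; with one recording per infant the random effect is
then unidentifiable and the model is fitted as ordinary least squares,
flagged as such.

## The synthetic generator

The generator emulates the signal properties the detection and
quantification stages rely on, with every injected effect recoverable:

* **Respiration**: a frequency-wandering carrier near 0.75 Hz whose
  envelope collapses to 2% (chest-wall stillness) inside pauses, plus
  Gaussian noise (SD 0.05 of the breath amplitude). Requested pause
  onsets/offsets are snapped to breath-cycle times, so the ground-truth
  interval endpoints coincide with the last breath before and first breath
  after the cessation — the quantity an inter-breath-interval detector can
  actually recover. Pause durations are drawn log-uniformly over 6–40 s
  (so both categories occur, with short pauses in the majority, as in
  clinical cohorts) and placed with at least 180 s separation by default so
  events are isolated by construction.
* **EEG**: per-channel 1/f-amplitude noise (power slope ≈ 1 over
  0.5–30 Hz, matching the low-frequency dominance of infant EEG) scaled to
  30 µV RMS, multiplied by 10^(suppression) during each pause. The
  suppression persists 5 s past the pause end by default, reflecting the
  observation that cortical recovery lags the breath; an optional pre-onset
  ramp exists but is off by default so null simulations are exactly null.
* **Vitals**: heart-rate baseline drawn per infant from 120–170 bpm with
  slow wander; Gaussian-shaped dips with nadir 10 s (HR) and 25 s (SpO₂)
  after the pause end, depths linear in pause duration (1 bpm/s and
  0.4 %/s), the SpO₂ floored at 60%. The HR coupling carries a per-infant
  random deviation (SD 0.2 bpm/s), giving the mixed models a true random
  slope. Severity is identified with duration — the simplest identifiable
  coupling.
* **Sleep**: a sticky four-state chain (TA/HVS/ASI/LVI) over 30-s epochs.

Each modality draws from its own derived RNG stream, so generating a
subset of modalities is still byte-reproducible.

What the generator does *not* emulate: real cardiorespiratory coupling
physiology, movement and electrode artifact structure, state-dependent EEG
spectra, or a true dependence of EEG suppression on sleep state and age.
Passing recovery tests therefore demonstrates that the pipeline measures
what was injected under realistic noise — not that clinical effect sizes
will match.

## Problem sizes and numerical choices

Validation uses cohorts of 10–20 infants with 15–30-minute recordings and
2–3 channels, which already yields 30–120 events — enough for the paired
t-maps and slope-recovery checks while keeping a full run in the order of
a minute. Mixed-model calibration uses 100 replicates of 60 infants × 20
events, the design under which two-standard-error coverage of the true
slope is expected near 95%.

Other fixed numerical choices: log₁₀ floor 10⁻⁶ µV; Hilbert/filter edge
discard 2 s (5 s padding on analysed segments); baseline-window ties break
to the earliest window; event windows are closed-open `[a, b)` in seconds
from recording start; the breath-detector refractory gap is 0.5 s.

## Known limitations

* The classifier is trained on generated candidates; with real labelled
  data its headline accuracy will differ.
* The SpO₂ floor censors severe desaturations; no correction is attempted.
* Channel-wise ±500 µV rejection is cruder than expert visual screening
  for apnoea epochs.
* Periodic breathing / clustered pauses are excluded by design, not
  analysed.
* With one recording per infant the PMA model carries no random effect.
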