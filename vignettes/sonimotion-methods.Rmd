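---
title: "Movement sonification: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement sonification: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonimotion)
```

sonimotion implements the software of two movement-sonification devices for
captive primates — a wired strain-sensing surface and a wireless
accelerometer toy — together with their calibration analyses, logging, and
seeded synthetic generators that stand in for the hardware. This vignette
explains the underlying models, the parameters that matter, and the design
decisions taken where the problem was genuinely open.

## The wired pipeline: two-stage thrust detection

Four piezoelectric sensors under a rigid surface each yield a 10-bit count
(0–1023); the acquisition layer reduces a frame to the sum of the four
channels, bounded by 4092. The species-typical manipulations separate by
magnitude — touch < tap < hit ≤ thrust at onset — but hit and thrust peaks
overlap, so a single amplitude threshold cannot distinguish a superficial
strike from the surface-displacing push that should sound. What separates
them is time: a thrust keeps loading the sensors, so its summed signal is
still high ~5 ms after onset, while a hit has already decayed.

The detector therefore uses two thresholds separated by a delay:

1. a candidate opens when a frame's sum exceeds `stage1_threshold`
   (default 1000 counts);
2. the sum is re-read `stage2_delay_ms` (default 5 ms) later and the event
   is confirmed iff that second sum exceeds `stage2_threshold` (default
   1765 counts — the lower 95% confidence bound of the thrust profile at
   5 ms, see below);
3. a confirmed event imposes `refractory_ms` (default 300 ms) during which
   no candidate may open, so one manipulation elicits one sound.

Numerical choices worth stating:

* **Strict inequalities at every threshold.** A sum exactly at a threshold
  does not pass; the boundary behaviour is pinned by tests (a constant
  stream at the noise-gate value produces nothing).
* **"Re-read after 5 ms"** is implemented as *nearest frame at or after*
  `t + stage2_delay_ms`; if none arrives within twice the delay the
  candidate is abandoned. Recorded streams can drop samples, and
  confirming against a frame far in the future would change the meaning of
  the test.
* **Refractory origin.** The refractory period is measured from the
  stage-1 trigger time of the last *emitted* event, because it models the
  acquisition loop stopping after a confirmed detection; failed candidates
  cost nothing.
* **Noise gate vs stage 1.** The 500-count noise gate (gentle touching
  reaches about 500) applies in recording/calibration mode; the live
  detector's stage-1 threshold of 1000 subsumes it.

The serial transport contract is part of the pipeline: confirmed sums
travel as ASCII decimal lines, and `parse_serial_line()` accepts a line
iff it is digits surrounded by optional whitespace — corrupted lines are
data to be discarded, not errors.

`sensor_layout()` gives the sensor placement: positions inducing a
centroidal Voronoi tessellation of the surface, so each sensor sits at the
center of mass of its own tile. For the deployed 4-sensor rectangle this
is the analytic quadrant-centroid layout; the generic case runs Lloyd
iteration on a discretised rectangle, and `lloyd_step()` is exported so
the fixed-point property is directly testable. Coordinates are
corner-origin millimetres, x rightward, y upward.

## The wireless pipeline: jerk and the continuously reset timer

The wireless device reports 3-axis acceleration as 8-bit counts every
10 ms over a ±3 g range. Because a carried device accelerates constantly
(gravity, gait), the pipeline works on the *change* in acceleration:
per-axis deltas of consecutive samples, collapsed to the Euclidean norm
(the jerk). Jerk is invariant under any constant per-axis offset, so
gravity and any linear systematic sensor error cancel exactly — the
property that makes the device usable without calibration — and walking
produces near-zero jerk while shaking produces large spikes.

Sample jerk is compared with `activation_threshold`; an activation is
sonified only if `refractory_ms` has passed since the *previous
activation*, and **every** activation — sonified or not — resets the
timer. This is the stricter of the two readings of a reset-on-activation
debounce, and it is a deliberate choice: a sustained shake produces one
sound and then silence until a quiet period elapses, which separates
"sound units" by periods of little movement instead of re-triggering at
the refractory rate.

The activation threshold has no published numeric value (the original
device exposed it as a live slider adjusted per individual). The default
of 30 raw counts was fixed once, so that the synthetic walking regime
stays well below it and shake bursts well above; it is fully configurable
and no quantitative claim depends on it. The wireless refractory value is
likewise unstated and defaults to the wired pipeline's 300 ms. Streams are
validated against the 10 ms cadence with a ±2 ms jitter tolerance.

## Calibration: segmentation, features, and the height regression

Drop sessions are segmented by inter-reading gaps. A reading at least
`onset_gap_ms` (2000) after its predecessor opens a trial; a reading
within `ricochet_gap_ms` (500) continues whatever its predecessor belonged
to; a reading in between is ricochet stress from the surface's rebound and
is discarded. A follower within 500 ms of a *discarded* reading is also
discarded: ricochet clusters are dropped whole, since reattaching an
echo's follower to the trial would contradict the offset rule. Every
reading lands in exactly one trial or the discard pile, and widening the
ricochet window can only retain more readings — both properties are tested.

Each trial is summarised by the mean of its first ≤10 samples ("up to the
first 10" is read as `min(length, 10)`), mirroring the real-time
constraint that playback cannot wait for a long trial. Features from
trials with known fall heights enter ordinary least squares,
`feature ~ height_cm`, reported with adjusted R², the F statistic on
(1, n−2) df, and t statistics for both coefficients.

The per-bin hit/thrust comparison in `profile_strain_types()` aligns each
repetition's first sample to t = 0, bins at 5 ms (the transmission
settings' maximum time resolution), and lets each repetition contribute
its within-bin mean. Confidence intervals are Student-t across
repetitions — the original analysis says only "confidence intervals", and
the t flavour is the standard choice at ~59 repetitions. The two-condition
test per bin is Welch's two-sample t-test with Satterthwaite df (sign
convention hit − thrust); the published description ("paired independent
samples adjusted for unequal variances") is internally contradictory, but
its reported fractional df identifies Welch. Bins with fewer than two
repetitions in either condition yield no test. The stage-2 threshold
recommendation is the thrust condition's lower CI bound at the bin
containing the confirmation delay.

## Synthetic generators: what they emulate, what they do not

`gen_strain_pulse()` produces piecewise-linear summed envelopes per
manipulation type, split equally over the four channels with independent
Gaussian noise (sd 3 counts per channel) and clipped to 10 bits. The
breakpoints encode the *defining* features — thrust above 1000 at onset
and above 1765 at 5 ms with a secondary rise at 70–95 ms; hit matching at
onset but below 1765 from 5 ms on; tap peaking between the 500-count gate
and stage 1; touch below the gate throughout — because no waveform data
for the real sensors is published. The inequalities are contract
(violating them by rescaling is an error); the exact envelope values are
convention. Per-channel equality is likewise a simulator convention: no
per-channel profiles exist to emulate.

`gen_drop_session()` reproduces the calibration protocol: nine heights
(20–180 cm) × five drops, onsets separated by more than 2 s, 15 samples
per trial 40 ms apart, and optional ricochet echoes 600–900 ms after the
preceding reading (inside the discard window by construction). A trial's
mean is `1208.29 + 3.00·d` plus trial-level noise; within a trial, samples
follow a fixed zero-mean decay shape over the first 10 samples, so the
noiseless limit recovers the line to machine precision. The default
residual sd (~138 counts) is not invented: it is computed at run time from
the target adjusted R² of 0.56 and the fixed design via
R² = SS_model / (SS_model + (n−2)σ²). The generator does *not* model piezo
electromechanics, channel cross-talk, or the quantisation of the summed
value (sums are returned as analogue counts; rounding them would break the
exact noiseless limit while changing nothing else detectably).

`gen_accel_stream()` encodes zero g near 128 counts with ≈42 counts per g:
rest is baseline plus unit noise; walk adds a 800 ms sinusoid (amplitude
12 counts) on one axis plus the gravity offset, keeping jerk ~1–3 counts;
shake superimposes alternating ±60-count excursions for 60 ms at the
requested burst times (jerk ≫ 100). Real chimpanzee locomotion and
manipulation are far richer; what these regimes establish is that the
*detector logic* discriminates the regimes the device was designed around,
not that the threshold transfers to a given animal.

All generators take a `seed`, are bit-reproducible under it, and restore
the caller's RNG state.

## Sonification and logging

`sound_mapping()` maps event kind and magnitude range to a sound id and a
gain; gain curves are constant, linear in magnitude (the natural
jerk→intensity mapping), or user breakpoints, always clipped to [0, 1] and
monotone by construction. Sounds are referenced by id only; playback sinks
are pluggable (`null_sink()`, `file_sink()`), and dispatch returns one
playback record per trigger with measured latency. Session logs are
single-file CSVs whose '#'-prefixed header blocks record every active
parameter; reopening after a parameter change appends a new block, so the
file carries its own parameter history. Wireless-style `"immediate"` mode
writes each row as it happens (rows survive a crash); wired-style
`"buffered"` mode flushes at session close. Logs round-trip exactly.

## Behavioral annotation summaries

`parse_annotations()` reads a tab-delimited export of time-aligned
behavior coding (individual, behavior, start, end, optional sound
condition) against a fixed vocabulary; poke, push and hit are point events
(start = end) and durations are meaningful for proximity. `summarize_behaviors()`
builds the per-individual interaction table with a totals row; proximity
is summed per individual independently, so the group total may exceed the
session length when individuals overlap — that is a feature of the
measure, not a bug. The shipped pilot fixture
(`extdata/pilot_annotations_synthetic.tsv`) is synthetic: its counts and
proximity durations match the published pilot-session table, but all
within-individual event times are invented.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale: 45-trial
calibration sessions (~730 readings), 100-seed parameter-recovery loops,
59-repetition profiles, 200-pulse detector stress mixes, and oracle
comparisons on streams of a few hundred samples — sizes at which the
brute-force oracles are exact and the whole suite completes in well under
a minute.

Known limitations: the detectors are offline scans over recorded frames
(the real-time contract is expressed as a per-event latency bound on
mapping + dispatch, tested softly); no audio device is driven — the
playback contract stops at the record a sink receives; the published
regression statistics and the hit/thrust t value depend on unpublished
raw sensor data, so the package claims parameter *recovery* on synthetic
sessions and a qualitative (|t| > 2) profile separation, not a numeric
reproduction of those statistics.
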