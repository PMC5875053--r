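---
title: "Adaptive-threshold QRS detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold QRS detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsdetect)
```

## The detection problem

An ECG records the heart's electrical activity as a quasi-periodic signal in
which each beat contributes a P wave (atrial depolarisation), the dominant
QRS complex (ventricular depolarisation) and a T wave (repolarisation).
Locating the QRS of every beat — and from it the RR interval sequence — is
the prerequisite for rhythm analysis. Ambulatory (Holter) recordings add
three noise classes: baseline drift (respiration and electrode motion,
< 1 Hz), powerline interference (50/60 Hz) and broadband EMG noise. An
adaptive-threshold detector handles all three with a handful of integer
filters and a small state machine, which is why this family dominates
portable and wearable devices.

## Preprocessing cascade

Five stages transform the raw signal `x(n)` into a non-negative envelope in
which beats are smooth humps:

* **Low-pass** `y(n) = 2y(n-1) - y(n-2) + x(n) - 2x(n-6) + x(n-12)`: the
  recursive form of the FIR `(1-z^-6)^2/(1-z^-1)^2` — a triangular impulse
  response `1,2,…,6,…,2,1` with DC gain 36, cutting powerline and EMG
  components.
* **High-pass** `y(n) = 32 x(n-16) - s(n)` with the running 32-sample sum
  `s(n) = s(n-1) + x(n) - x(n-32)`: a delayed all-pass minus a moving
  average, with exactly zero DC gain, removing baseline drift. The recursion
  is sometimes printed with `s` and `y` conflated into one symbol; read
  literally that variant has DC gain 16 and an oscillatory pole at z = −1,
  so this package implements the two-filter reading, the only one whose
  response removes baseline wander.
* **Derivative** `(1/8)[-x(n-2) - 2x(n-1) + 2x(n+1) + x(n+2)]`: emphasises
  the steep QRS slopes over the gentler P/T slopes. The textbook form uses
  two future samples; we apply it causally and book the extra 2 samples as
  delay.
* **Squaring**: makes everything positive and quadratically favours large
  slopes.
* **Moving-window integration** over 24 samples (66.7 ms at 360 Hz),
  normalised by 1/N: collects slope energy over roughly one QRS width, so
  each beat becomes a single hump whose width also encodes QRS duration.

### Delay bookkeeping

Detections are made on the integrated signal and mapped back by
subtracting the cascade delay. The per-stage ledger is
lowpass 6 + highpass 15 + derivative 2 + integration `floor(N/2)` = 35
samples at 360 Hz. The individual low-/high-pass figures are the
conventional ones for these filters; measured from the impulse responses
the centres are 5 and 16 respectively — off by one each, in opposite
directions — so their *sum* (21 samples), which is all the fiducial
correction uses, is exact; the test suite pins both the conventional
per-stage values and the measured ones so the discrepancy stays visible.
A final refinement snaps each corrected fiducial to the largest-magnitude
band-passed sample within ±10 samples (28 ms), which absorbs the rounding
of the integration delay and startup transients; on noise-free synthetic
records the result lands within one sample of the true R position.

### Sampling-rate generality

All filters keep their 360 Hz integer coefficients (they *are* the design),
while window-style constants — integration width 24, initialisation window
300, merge distance 80, forcing interval 300, timeout 400 — are rescaled by
`fs/360`, so other rates work with proportionally identical behaviour. No
amplitude normalisation is applied before filtering; the decision rule is
scale-invariant (a property test verifies this), so none is needed.

## Candidate peaks

The scan keeps a running maximum since the last emission and emits it as a
candidate when the signal drops below half of it (the running maximum then
restarts at the current sample — without a reset the half-drop rule cannot
fire twice). If 300 samples pass without any emission, the maximum of the
whole unemitted stretch is emitted and flagged `forced`; the counter resets
on every emission. "Local max on timeout" is interpreted as the maximum of
the unemitted stretch rather than of a trailing fixed window — on the flat
or slowly varying signals where forcing matters the two coincide, and the
stretch reading never skips a sample. Finally, peaks closer than 80 samples
(222 ms, under any plausible refractory period) are merged iteratively,
keeping the larger amplitude (ties keep the earlier). Forced peaks on flat
signal are deliberately *not* suppressed here: the peak stage is
threshold-free by design, and the adaptive threshold rejects them later.
T waves regularly produce small genuine candidates — roughly 1% of the QRS
hump after squaring — and serve as the noise population that keeps NPK
calibrated.

## Adaptive threshold

State: signal-peak estimate SPK, noise-peak estimate NPK, decision level
`THRESHOLD = 0.25 SPK + 0.75 NPK` (an invariant re-established after every
update), a 10-slot FIFO of accepted RR intervals with mean `AVE_RR`, and
the last accepted QRS position. Initialisation uses the first 300 samples
of the integrated signal: `SPK = 0.13 max`, `NPK = 0.1 SPK`.

Candidates above THRESHOLD (strictly — ties reject, for determinism) are
accepted and update `SPK ← 0.125 peak + 0.875 SPK`; the rest update NPK the
same way. The 0.125/0.875 exponential refresh is the classic smoothing for
this detector family; the update rule for NPK (smoothed, not overwritten)
follows the same convention. Both are exposed as `smoothing_factor` in
`detector_config()`.

**Search-back.** Hearts do not stop between candidates: if the gap since
the last beat exceeds `max(400 samples, 1.5·AVE_RR)` — 400 samples alone
until the first RR exists — SPK is halved, THRESHOLD recomputed, and the
*rejected* candidates inside the gap are re-scanned in order; the first to
clear the lowered threshold is accepted and flagged. Halving repeats while
the gap persists, stopping early when even `THRESHOLD → 0.75·NPK` could not
accept the best remaining candidate (this bound also guarantees
termination). The `1.5× RR` factor is applied to AVE_RR, the only RR
statistic the state defines; taking the larger of the two limits prevents
spurious halving during legitimately slow rhythms. The same check runs once
more at the end of the record so a final weak beat is not stranded. The
deliberate cost of this aggressiveness: in a gap where a beat is truly
absent (not merely small), search-back will eventually accept a T wave or
noise hump — a false positive inside an already-flagged abnormal region.

## Reporting

Any RR interval strictly over 1000 ms (exactly 1000 ms is normal — the rule
is "no QRS found *in* 1000 ms") becomes a suspicious region spanning the two
bounding detections in raw coordinates — the interval, rather than a single
pointer, is what a reviewer needs to window the strip. RR intervals are
always computed from delay-corrected raw fiducials, never integrated-signal
positions. The RR-Lorenz plot pairs `x = RR(N)` with `y = RR(N+1)` in ms
(count = #RR − 1); `render_reports()` writes region PNGs (±5 s of context, a
compromise between strip readability and file count), the Lorenz scatter and
CSV, and a JSON summary.

## Evaluation

Detections match reference beats one-to-one within ±150 ms, the ANSI/AAMI
EC57 window (the matching tolerance is not part of the detector and is
configurable). Matching is earliest-eligible greedy over sorted sequences —
for interval tolerances this attains the maximum possible number of pairs
(the classical convex-bipartite matching argument), and a property test
checks it against exhaustive assignment on small instances; nearest-first
greedy, by contrast, can lose a pair. Reference annotations are first
filtered to the standard WFDB beat codes (`wfdb_beat_codes()`), since
rhythm and quality annotations are not beats. Reported figures:
`Se = TP/(TP+FN)`, positive predictivity `Sp = TP/(TP+FP)` (widely labelled
"specificity" in this literature; the alias is kept with this caveat),
`detection rate = (actual − FP − FN)/actual` and `Er = (FP+FN)/actual`.
Batch aggregates sum counts across records and recompute rates from the
sums — never averaging per-record rates.

## Synthetic records

`generate_synthetic()` emulates what the detector actually consumes, not
cardiac electrophysiology. Per beat: a Gaussian QRS bump with σ = 25 ms —
its spectral energy sits under ~13 Hz, inside the 5–15 Hz band the cascade
passes — plus a P bump (0.15 mV, σ = 40 ms, 160 ms early) and a T bump
(0.3 mV, σ = 70 ms, 300 ms late). Defaults: 360 Hz, 72 bpm, 5% RR jitter,
0.1 mV drift at 0.33 Hz, 0.02 mV powerline at 50 Hz, 0.02 mV white noise —
typical resting-Holter figures; amplitudes in mV on a ~1 mV R wave. Dropped
beats are removed from signal *and* ground truth (leaving the RR gap);
attenuated beats are scaled but keep their annotation, which is exactly the
search-back scenario. Generation is a pure function of (spec, seed) with no
global RNG state.

What the generator does **not** model — QRS morphology variants (notches,
Q/S waves), pathological rhythms, electrode motion artefacts, tall-P-wave
records — bounds what green synthetic tests prove: they validate the
mechanics (each rule firing when and only when constructed to), not
benchmark performance on real arrhythmia data, which requires the standard
annotated database and is kept out of the default test run.

## Numerical and degenerate-input choices

* Filter startup: missing history is zero; transients settle within one
  filter length and tests assert steady-state behaviour past them.
* All-zero signals: `M_VAL = 0` gives `SPK = NPK = THRESHOLD = 0`; forced
  peaks of amplitude 0 fail the strict `>` test and are rejected — no
  detections, by construction rather than by special-casing.
* Records shorter than the initialisation window use all samples.
* SPK/NPK have a floor of 0 and no ceiling; halving cannot cross zero.
* Ties: equal-amplitude merges keep the earlier peak; threshold ties
  reject; `which.max` takes the first position on plateaus. Every
  tie-break is deterministic.
* Fiducial indices are clamped to signal bounds after delay subtraction.

## Problem sizes in the tests

The default suite runs entirely on generated data: property tests use
30–40 random arrays of ≤ 500 samples, end-to-end tests use 10–120 s
records, and one 5-minute clean record checks sustained Se = 100% with zero
false positives — sizes chosen so the full suite stays well under a minute
while still exercising every rule (a 5-minute record crosses the RR-buffer
fill, both timeout limits and several thousand candidate decisions).

## Known limitations

* The WFDB reader covers single-`.dat` records in formats 212/16/80 — the
  MIT-BIH layout — not multi-segment or multi-file records.
* The detector is single-channel; on two-channel records it defaults to the
  first channel (MLII in most MIT-BIH records), overridable via
  `detector_config(channel = …)`. Which channel the benchmark results used
  is not documented; channel 1 is this package's choice.
* Search-back inside genuinely empty gaps trades false positives for
  sensitivity (see above); applications that prefer silence can raise
  `rr_gap_factor` or disable halving via `searchback_halving = 1`.
* No beat-type classification: every detection is reported as a plain QRS.
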