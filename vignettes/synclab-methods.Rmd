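---
title: "Validating multistream acquisition by simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multistream acquisition by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synclab)
```

# The problem

Wearable acquisition platforms collect many concurrently sampled streams —
EEG, accelerometers, markers — from devices with independent clocks joined by
wireless links. Two distinct timing errors corrupt such recordings:

1. **Clock disagreement**: each device stamps samples with its own clock,
   which differs from the collector's by an initial offset, drifts at tens of
   parts per million, and adds per-sample jitter. Streaming middleware
   measures the momentary clock offset of each device at periodic intervals,
   so this error is observable and correctable post hoc.
2. **Transport latency**: wireless links (Bluetooth, proprietary WiFi) delay
   the *content* of a stream by tens of milliseconds without touching its
   timestamps. This delay is invisible to clock synchronization, changes at
   every device startup (handshake renegotiation), and must be estimated
   physically — here by applying a shared mechanical perturbation to all
   devices and cross-correlating their accelerometer streams.

`synclab` implements both corrections and the downstream EEG validation
pipeline as a fully simulation-driven package: every input can be generated
with known ground truth, so each stage is testable without hardware.

# Clock model and synchronization

A device's raw timestamps follow

$$ t_{raw} = t_{ref}\,(1 + \delta) + o_0 + \varepsilon, $$

with drift $\delta$ (dimensionless, ppm-scale), initial offset $o_0$ and
jitter $\varepsilon \sim N(0, \sigma_j^2)$. The collector's offset
measurements $(t_i, o_i)$ are fitted with a linear model; shared time is
$t_{raw} - (\hat{o}_0 + \hat{\delta}\,t_{raw})$. Because the correction is
evaluated at the raw time rather than the unknown reference time, a
second-order error of order $\delta^2 t$ remains (about 6 µs over ten
minutes at 100 ppm) — far below the millisecond scale of interest.

**Robust fit.** The slope is the Theil–Sen median of pairwise slopes;
measurements whose residual exceeds 5 robust standard deviations are then
dropped and the intercept is the mean residual of the inliers. The
median-of-slopes step tolerates the gross outliers that wireless handshake
transients produce; the trimming step keeps the *intercept* robust as well,
which a plain least-squares intercept over all points would not be.

**Dejittering** splits a stream into contiguous segments wherever the
inter-sample gap exceeds `max(2 / rate, 10 ms)` (the convention of common
session-file loaders) and replaces each segment's timestamps by its
least-squares line in sample index. Timestamps are then exactly equispaced
per segment; with 1 ms jitter at 500 Hz over a minute the reconstructed grid
is within 0.05 ms RMS of the truth.

**Offset-measurement cadence.** The measurement interval is a parameter
(default 5 s) with Normal(0, 0.2 ms) measurement noise; these defaults
exercise drift fitting without making it trivial. They are a simulation
choice, not a claim about any specific middleware.

# Perturbation calibration

Transport latency is estimated from the accelerometer streams all devices
carry. The simulator's bench stimulus is Gaussian baseline noise, impulsive
Gaussian strokes along random 3-D directions, and windows of band-limited
random movement (both stimulus types matter: movements are easy for an
operator to produce, strokes give sharply re-alignable features). The
estimation chain is:

* **magnitude**: per-sample Euclidean norm across axes, mean-removed —
  invariant to how each device is mounted;
* **resampling** of all magnitude traces onto a common 1 kHz grid by linear
  interpolation over the intersection of supports; samples adjacent to
  transport losses are marked invalid and excluded from correlation rather
  than interpolated across, so no signal is fabricated;
* **chunk detection**: windows where the 100 ms moving RMS exceeds the
  trace's median + 10 MAD (merged below 200 ms gaps, dropped below 100 ms);
  at this threshold the false-positive rate on pure noise is below 1%;
* **lag estimation**: per chunk, the argmax of the normalized
  cross-correlation between the reference chunk and lag-shifted segments of
  the other trace, over ±500 ms at 1 ms resolution (no sub-sample
  interpolation — the reported offsets are integer milliseconds at the 1 kHz
  analysis rate). The comparison segment is drawn from the full trace, so
  short impulsive chunks pose no problem; a chunk is skipped only when it
  lies closer than the search half-window to the trace edge. Per-chunk lags
  are combined by their mean (median available).

The **sign convention** is: positive lag means the other stream *trails* the
reference (its content arrives later). Offsets are averaged across sessions
into a matrix with mean, across-session sd, and the sample-equivalent
`round(mean_ms * rate / 1000)` of the receiving stream; the mean matrix is
antisymmetrized as $(M - M^T)/2$. Compensation subtracts the calibrated
offset from each stream's shared timestamps. Because latencies are redrawn
at every startup, the end-to-end benchmark compensates each session with its
own calibration; the across-session matrix documents typical offsets and
their restart variability.

Recovery accuracy at the bench conditions (four devices, latencies of a few
tens of ms, drift ≤ 50 ppm, 1 ms jitter) is well inside ±2 ms per pair, with
post-compensation residuals ≤ 1 ms; a 25 Hz stream recovers within half its
40 ms sampling interval.

# Synthetic EEG

Seven channels (Fpz, Fz, Cz, Pz, Oz, C3, C4) at 500 Hz. Background activity
is 1/f (power slope −1) plus white noise in 0.8/0.2 power proportion, scaled
to a total RMS (`backgroundNoiseUv`, default 8 µV) and multiplied by the
device profile's noise factor (`egi_like` 1.0, `biohub_like` 1.5 with
transport losses enabled — the wearable dry-electrode system is noisier than
the lab reference). Equal seeds produce the identical noise realization
across profiles, scaled, so profile comparisons are paired.

Task features, each at its physiological site:

* **Eyes open/closed**: a 10 Hz oscillation at Oz (half weight at Pz) whose
  amplitude switches between `alphaOpenUv` (2 µV) and `alphaClosedUv`
  (8 µV) — a typical 3–4× reactivity.
* **Motor**: a dedicated 10–20 Hz sensorimotor oscillation at C3/C4/Cz whose
  amplitude is multiplied by $\sqrt{1 - \mathrm{erd}}$ during movement, so
  the event-related spectral perturbation in that band reads
  $10\log_{10}(1-\mathrm{erd})$ (−3 dB at the default 0.5). The rhythm RMS
  default is 12 µV, at the upper end of idle-rhythm amplitudes; at that
  level the rhythm dominates its band and the measured ERSP sits within a
  few tenths of a dB of the closed form, which is the design intent of a
  generator with a *controllable* effect size.
* **SSVEP**: a sinusoid at twice the checkerboard modulation frequency
  (10/12 Hz for 5/6 Hz modulation) at Oz, 0.4 weight at Pz, default 5 µV —
  mid-range for pattern reversal, and chosen so the steady-state line
  dominates the occipital Welch spectrum over the 1/f floor for every seed,
  which is the qualitative signature the validation reproduces.
* **Oddball**: a Gaussian-envelope positive deflection at Cz (0.8 at Pz)
  peaking at `p300LatencyMs` (300 ms, constrained to [250, 400]) with 60 ms
  width and 5 µV peak on target stimuli only, plus a small early visual
  response at Oz for every stimulus.

Protocols match the validation designs exactly: 10 repetitions of 5 s
open / 5 s closed; 25 clutching trials of 4 s with uniform 8–12 s rests;
three 10 s runs per modulation frequency with 7 s rests; five oddball runs
of 10–12 targets with 200 ms stimuli and 400 ms ISI. Each session starts
with a free-blinking period (default 60 s; shorter in tests) used for blink
identification.

**Oddball pairing.** The task's stated 1/5 target/non-target ratio is
inconsistent with its printed pairing of 10–12 targets with 60–72
non-targets (which is 1:6). The generator follows the printed pairing,
`nonTargets = 6 * nTargets`; the 1/5 figure is treated as nominal. Target
order is randomized with no two consecutive targets (standard oddball
practice), by placing targets into distinct gaps of the non-target sequence.

**Artifact injectors** mirror the rejection rules: stereotyped 300 ms
biphasic blinks with a front-to-back gradient maximal at Fpz; lost-sample
runs marked in the lost mask; 300 ms amplitude bumps exceeding ±50 µV; and
saturation-like drift segments in which the electrode signal collapses onto
a near-linear ramp with a 10% residual of the original activity. The
saturation form matters: an *additive* ramp large enough to reach
r² > 0.85 over an epoch with ≥ 6 µV noise would necessarily violate the
±50 µV amplitude bound first, making the linear rule unreachable. Every
injection is logged, giving ground truth for rejection tests.

# Validation pipeline

**Preprocessing.** Validation mode: common-average reference, then zero-phase
band-pass 1–30 Hz; BCI mode: no re-reference (ear-referenced montage),
0.1–30 Hz. The band-pass is a cascade of order-4 Butterworth high-pass and
low-pass filters run forward-backward; the cascade keeps the 0.1 Hz lower
edge numerically stable at 500 Hz in transfer-function form, and zero-phase
filtering preserves ERP latencies. The analytic stop-band attenuation of
this design at 50 Hz is $2 \times 10\log_{10}(1 + (50/30)^8) \approx 36$ dB.

**Blink removal.** Blinks are detected on Fpz as robust-z excursions above 3
that last at least 20 ms (physiological blinks are sustained 100–300 ms
events; the duration criterion stops single-sample noise tails from being
treated as blinks). Detection windows are ±200 ms around each excursion; the
first principal component of the concatenated windows across channels is
projected out of the whole recording (one component — the number is an
assumption). The projector is computed and applied *before* common-average
referencing: after CAR, the blink's frontal gradient becomes a montage-wide
pattern with a large occipital weight, and projecting it out removes roughly
half the occipital alpha power; on unreferenced data the alpha change is
around 1%.

**Epoching** uses the task windows verbatim: [0.5, 5] s for eyes; [0, 4] s
move and [2, 6] s rest for motor; three 50%-overlapping 5 s epochs per 10 s
SSVEP trial; [−0.2, 0.7] s with [−0.2, 0] s baseline for oddball; [0, 0.7] s
with the first 100 ms as baseline in BCI mode. Markers whose window exceeds
the recording are skipped with a warning.

**Rejection** applies four rules in order — loss (strictly more than 20
consecutive lost samples), amplitude (outside ±50 µV; ±100 µV in BCI mode),
PSD (band-mean multitaper density over 20–30 Hz above 60 dB re 1 µV²/Hz),
linear (any channel's amplitude-vs-time r² above 0.85; constant channels
define r² = 0) — recording the first rule each epoch trips. BCI mode uses
only loss and amplitude. Two structural facts are worth knowing. First, with
the 1 µV²/Hz reference, a signal inside ±50 µV can never reach a 60 dB band
mean, so the PSD rule only fires on near-rail segments and never *before*
the amplitude rule under default thresholds (the dB reference of this rule
is genuinely underdetermined; the implementation keeps the threshold
configurable). Second, a 1 Hz high-pass removes within-epoch linear ramps
almost entirely, so the linear rule is exercised on unfiltered data — which
is where saturation-like drift lives. The manual-validation step of the
semi-automatic procedure is replaced by `rejectionReport()`, a dry-run
listing of flagged epochs.

**Spectral estimation.** Welch uses the quoted parameters literally: Hanning
window, 2000-sample segments, 1000-sample overlap, 5000-point FFT — a
0.1 Hz grid at 500 Hz, two windows per 5 s epoch, one per 4–4.5 s epoch.
Multitaper uses DPSS tapers with half-bandwidth 2 Hz and non-adaptive
weights (the half-bandwidth is a choice; none is quoted). Tapers come from
the tridiagonal concentration matrix, computed exactly up to 1200 samples
and interpolated from 1024 with re-orthonormalization above that — the
classic shortcut, with negligible concentration loss for band-averaged
PSDs. Densities are one-sided µV²/Hz; dB is $10\log_{10}$(PSD / 1 µV²/Hz).

**Time-frequency maps** use complex Morlet wavelets at 1..30 Hz with cycle
counts 1..30 matched index-wise (a constant ~0.16 s temporal sigma across
frequencies), power averaged over trials and converted to dB against the
mean of the [−6, 0] s pre-event baseline per frequency.

**Statistics.** Bin-wise comparisons are two-sided Welch t-tests with
Bonferroni correction at α/m. The cluster-mass test thresholds
dependent-sample t values at the two-sided α = 0.05 quantile, sums t within
same-sign clusters, and builds the null from sign-flip permutations of the
paired differences — exhaustively when $2^n$ does not exceed the requested
permutation count, otherwise by 1000 random flips with the standard
$(b+1)/(m+1)$ p-value. Empirical type-I error at the defaults is within
[0.03, 0.07].

**Power curves** draw n trials per condition without replacement (the
natural reading of trial subsampling against a finite recorded pool),
compute the per-trial scalar feature — the PSD peak in 8–12 Hz at Oz (eyes),
8–12 Hz at C3/C4 (motor), at 10/12 Hz at Oz (SSVEP), or the P300 peak in
250–550 ms at Cz (oddball) — and test the two conditions with a two-sided
t-test (independent, Welch; whether the original analysis paired subjects is
not stated). The proportion of significant draws per n and the smallest n
reaching 80% (`n80`) are reported. A caveat the implementation makes
explicit: when n approaches the pool size the subsamples nearly coincide
with the fixed pool, so per-dataset proportions under the null are bimodal;
only the *mean across datasets* (or small n relative to the pool) tracks α.

# What the simulations do and do not show

The generator reproduces the structure the pipeline is sensitive to —
rhythms with state-dependent amplitude at the right channels, stimulus-locked
deflections, 1/f noise floors, transport losses, blinks with a spatial
gradient, device-dependent noise scale — and the qualitative orderings that
follow (the noisier profile needs at least as many trials to reach 80% power
on the time-domain P300 feature; spectral features reach it with fewer trials
than time-domain ones). It does not model volume conduction, electrode
impedance dynamics, real artifact morphology beyond the stereotypes, or
between-subject variability; passing tests therefore validate the
*machinery* — estimators, rules, statistics, bookkeeping — not the
physiological claims, which require real recordings and the actual hardware.

Problem sizes in the test-suite and acceptance runs are scaled to desk
conditions as the package's own choice of study size: sessions of 12–20 s
with 4–5 strokes for calibration, 4 cold-restart sessions, shortened
free-blinking periods (10–30 s), 150–200 subsampling permutations, and 500
null datasets with 200 sign-flip permutations for the calibration property.

# Session container

Sessions are written as a single self-describing JSON document (one object
per stream: device spec, samples, raw/shared timestamps, lost mask,
clock-offset history, plus the simulation ground truth as a sidecar field,
since no standard session format carries ground truth). Numbers round-trip
at full precision; files from other producers are accepted when they carry
the same stream fields, and a stream without an offset history reads
successfully but is flagged unsynchronizable. Benchmark configurations are
YAML with schema validation; reports are CSV plus a plain-text summary
embedding the seed and a config hash, so a benchmark is reproducible from
its report alone.
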