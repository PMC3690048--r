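---
title: "Methods: wavelet R-peak detection, rhythm rules, and per-user SCR stress trees"
author: "cwtcardio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet R-peak detection, rhythm rules, and per-user SCR stress trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwtcardio)
```

cwtcardio analyses two physiological channels recorded by inexpensive wearable
hardware: a single-lead ECG sampled at 250 Hz (4 ms per sample, 0.013405 mV
resolution, 0-50 mV range) and a skin conductance response (SCR) channel
sampled at 4 Hz through a resistive voltage divider (0.573 mV ADC step,
2.35 V full scale). From the ECG it extracts R peaks, premature beats
(extrasystoles), arrhythmic RR transitions and heart-rate variability; from
the SCR it trains per-user decision trees that separate stress from relax
samples. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic test bench does and does not show.

## R-peak detection by continuous wavelet transform

The detector correlates the ECG with scaled, shifted copies of the Coiflet-5
mother wavelet,

$$C(a,b) = \frac{1}{\sqrt{a}}\int_{-\infty}^{\infty} x(t)\,
\psi^{*}\!\left(\frac{t-b}{a}\right)\,dt ,$$

with scale $a$ in sample units and shift $b$ on the sample grid. We adopt the
standard $L^2$ prefactor $1/\sqrt{a}$; the choice affects only the absolute
coefficient scale, never the window-normalized detection that follows.

**Wavelet construction.** No wavelet library is assumed: $\varphi$ and $\psi$
are built at load time from the published 30-tap orthonormal Coiflet-5 filter
by fixed-point iteration of the two-scale refinement relation on a dyadic
grid over the support $[0, 29]$ (40 iterations; successive iterates agree to
$10^{-11}$ well before that). The tabulated $\psi$ has unit $L^2$ norm and
zero mean to $10^{-6}$, and matches an independent wavelet library's
tabulation of the same filter to about $10^{-3}$ absolute — the residual is
the difference between the grid operator's fixed point and a finite dyadic
construction, and is irrelevant at detection scales.

**Discretization.** Coefficients are computed by FFT convolution with a
kernel that *integrates* $\psi$ over each sample cell (differences of the
cumulative integral of $\psi$), treating the signal as piecewise constant.
Compared with point-sampling $\psi$, this keeps small scales alias-free and
makes every kernel exactly zero-mean, so constant offsets and slow baseline
wander never leak into the coefficients. The record is extended by reflection
at both ends; zero extension would manufacture a large spurious edge response
that hijacks the normalization of the last window. The kernel is centred on
the dominant extremum of $\psi$ (x ≈ 14.5), which aligns the detection peak
with the R apex to within a couple of samples.

**Scale choice.** The analysis scale is fixed per record by a matched-filter
criterion over a small grid (`default_scales()`, spanning QRS-like durations
of roughly 20-120 ms at 250 Hz): among scales whose peak response is at least
1% of the grid's best, choose the one maximizing peak-to-RMS of the squared
coefficient series. Two failure modes dictate this form. Raw series energy
grows monotonically with scale and locks onto the broad, high-amplitude
T-wave scales. Pure impulsiveness measures (crest factor, peak/RMS alone)
lock onto degenerate *small* scales, where Coiflet-5's ten vanishing moments
annihilate a smooth QRS almost completely and the residue — tiny but spiky —
wins every normalized contest; the 1% response floor excludes exactly those
scales.

**Windowed thresholding.** The squared coefficients are processed in
non-overlapping 5 s windows (half-open; a final partial window is kept if at
least 1 s long), each normalized to maximum 1. Candidate beats are local
maxima separated by a 200 ms refractory period (a physiological minimum for
consecutive ventricular activations; the refractory also runs across window
boundaries, where a QRS straddling the cut could otherwise fire twice).
Candidates are compared on the *amplitude* scale — the square root of the
normalized squared series, i.e. $|C|/\max|C|$ per window — so that the
detector's amplitude bands act on the same scale as the ECG's own amplitude
ratios. Against a beat-level reference (by default the mean amplitude of the
window's candidates; the window maximum is available as a fallback
strategy), a candidate above 60% of the reference is an R wave and one in
the 30-60% band is a provisional extrasystole; the band edges are half-open
so the two classes partition the axis.

**Noise handling.** Two scale-invariant guards keep the detector silent on
beat-free input. A window is processed only if the 99.9th percentile of its
amplitude series exceeds 7 times its median: Gaussian-noise windows have
upper tails only ~5 times the median while QRS-bearing windows tower far
above it, and the high percentile (unlike the single maximum) cannot be
hijacked by one spike. Within a processed window, candidates must exceed
`min(7 × median, 0.35)`: on clean records the median term is minute and
low-amplitude extrasystoles pass untouched, while on noisy records the floor
rises with the noise level but is capped below the extrasystole band. A
record whose coefficients are pure floating-point residue (a constant
record) is recognized by an input-scaled epsilon floor. Consequences worth
knowing: with white noise at around 5% of the QRS amplitude the R waves are
still found reliably, but noise maxima can surface as spurious
provisional extrasystoles, and records with noise of 10% or more fail the
window gate entirely — this detector is built for the low-noise wearable
regime, not for stress-test noise levels.

## Beat classification and rhythm rules

Two ratio rules, applied to the beat times $t(i)$ exactly as stated (strict
inequality for the first, inclusive for the second pair):

* **Premature beat:** $[t(i)-t(i-1)] \cdot 2.2 < [t(i+1)-t(i)]$ — a beat that
  arrives early and is followed by a compensatory pause is an extrasystole
  even when its amplitude exceeds the 60% band.
* **Arrhythmia:** with $RR(i)=t(i)-t(i-1)$, flag interval $i$ if
  $RR(i) \ge 1.3\,RR(i-1)$ or $1.3\,RR(i) \le RR(i-1)$ — a 30% lengthening
  or shortening relative to the previous interval. The shortening inequality
  is read as $1.3$ multiplying the *current* interval, the symmetric
  counterpart of the lengthening rule ("30% over or less than the interval
  before"); the alternative precedence would make the rule asymmetric and
  fire on nearly every beat.

Both are pure ratio rules: time shifts and positive time rescalings change
nothing, and perfectly regular trains carry no flags. Flags are reported per
interval end-index (an index needs two prior intervals, so flags start at the
third beat); contiguous runs are merged into episode spans for reporting. The
first and last beats, untestable by the timing rule, keep their amplitude
class. The arrhythmia rule runs on raw RR intervals; the Hermite-interpolated
series below is used for reporting and plotting only.

## Heart-rate variability

`rr_from_beats()` anchors each interval at its ending beat. Uniform
resampling uses the shape-preserving piecewise cubic Hermite interpolant
(pchip: derivative limiting at the knots, zero slope at data extrema),
delegated to `pracma::pchip`. It passes through every knot exactly and never
leaves the local data range — the visually smooth, non-overshooting
variability curves this field plots — where an ordinary cubic spline
overshoots; R's `monoH.FC` Hermite variant was rejected because it only
guarantees monotone segments and measurably overshoots at data extrema. The
default resample rate of 4 Hz matches the SCR channel for joint plots.
`rr_stats()` reports the sample mean and SD (the $n-1$ denominator; with no
raw study data the convention is unverifiable against the printed deviations,
which are therefore never asserted) of raw RR within a protocol window, with
a toggle to instantaneous bpm since the printed tables leave the unit
unlabeled.

## SCR conversion and the per-user stress tree

The front end is a resistive divider: skin resistance $R_s$ in series with
$R_2 = 890\,\mathrm{k}\Omega$ across the supply $V_{cc}$ gives
$V_o = \frac{R_2}{R_s+R_2}V_{cc}$, strictly decreasing in $R_s$ — sweating
under stress lowers $R_s$ and raises $V_o$ by millivolts. The supply is not
printed and the two printed anchor points disagree (0.136 V at 10 MΩ implies
$V_{cc} \approx 1.664$ V; 1.755 V at 10 kΩ implies $\approx 1.775$ V), so
$V_{cc}$ is a config value defaulting to 1.775 V, the anchor with the larger
relative precision. ADC quantization is applied on synthesis only; analysis
accepts continuous voltages.

Because skin-response levels are not comparable across people, each subject
gets their own classifier; models never pool across users. The classifier is
a binary decision tree on continuous features (instantaneous voltage by
default; the slope, first difference × rate, is optional since the published
per-sample counts match voltage-only classification) grown by maximizing the
information gain *ratio* over candidate thresholds placed at midpoints
between sorted distinct values — the C4.5 family of splits. Growth stops at
purity, at `min_leaf` (default 2), or when no split has positive gain; ties
break to the lower threshold, making training deterministic. The tree is
unpruned by default (matching threshold-like per-user behaviour without
importing a Java toolchain); reduced-error pruning against a validation
record is available (`prune_stress_tree()`). On two equal-variance Gaussian
classes the root threshold estimates the Bayes boundary (the midpoint of the
means); with 400 samples, a 50 mV separation and 15 mV noise it lands within
a few millivolts.

Protocol labeling uses explicit labeled time spans rather than change
points, because the sounds protocol needs per-sound 15 s response spans with
unlabeled gaps between them. Constructors cover the two study protocols:
`stroop_schedule()` (task span = stress; relax = first 55 s, last 60 s, or a
custom span such as 15-55 s for a subject relaxed in neither) and
`sounds_schedule()` (only sounds the subject reacted to contribute stress
spans; lead-in/lead-out silences are relax).

## Confusion-matrix conventions

Tables use the convention row T/col P = TP, T/N = FN, F/P = FP, F/N = TN.
One naming trap is handled explicitly: the published tables' "Precision" row
equals overall accuracy $(TP+TN)/\text{total}$, not positive predictive
value — for the first R-wave table $117/117 = 1$ while the printed value,
0.9998, equals $33018/33024$ — so the package exposes `accuracy()` (and
`correct_rate()` = 100 × accuracy) for that quantity and `ppv()` under its
correct name. `pool()` sums counts; `mean_stat()` averages a statistic
unweighted; the published headline 99.42% is the unweighted mean of the
twelve per-user sensitivities. Beat scoring (`match_events()`) uses greedy
one-to-one matching within ±50 ms (a conventional beat-scoring tolerance;
optimal in cardinality for sorted lists) and counts TN at the sample level,
the convention under which the published TN entries approximate record
lengths in samples. Comparisons against printed values round half-up at the
printed precision. Two printed SCR correct rates (Stroop users 7 and 9)
disagree with their own count tables in the last digit — the user-7 row's
companion "Incorrect" entry confirms the matrix — so the matrix-derived
values are treated as ground truth there. The "Error"/"Success" rows of the
SCR averages follow an aggregate that is not derivable from the printed
matrices; they are read as inputs where needed and never recomputed.

## The synthetic bench

`gen_ecg()` places template beats — Gaussian P, QRS and T waves of relative
amplitudes 0.2/1/0.3 and widths of about 80/25/120 ms, 1 mV nominal R
amplitude — on an RR schedule: nominal rate, Gaussian beat-to-beat jitter,
inserted premature beats (interval in = prematurity × nominal RR; interval
out stretched to a full compensatory pause, so both rhythm rules fire by
construction when prematurity < 1/2.2), RR-multiplier episodes, sinusoidal
baseline wander and white noise. `gen_scr()` builds baseline + linear drift
+ stimulus-locked kernels (linear rise, exponential decay) + noise, clipped
to the ADC range, optionally quantized, with stress labels over the response
spans. All randomness flows from the single spec seed and the caller's RNG
state is restored afterwards.

The bench emulates the *structure* the detectors assume, not validated
electrophysiology: no QT adaptation, no respiratory modulation, no motion
artifacts, no electrode pops, and real extrasystoles change morphology, not
just amplitude. Passing the bench therefore demonstrates the algorithms'
contracts (detection, banding, rule logic, parameter recovery), not clinical
performance on recorded ECGs.

Default study conditions used by the tests and the acceptance script, chosen
once from the study's stated regime: 60 s records at 250 Hz across 50-120
bpm for detection sweeps (20 seeds); 120 s, 80 bpm, six premature beats at
amplitude ratio 0.45 and prematurity 0.4 for extrasystole runs; RR jitter
SDs of 0.089 s (before task) and 0.046 s (during task) for the
variability-ordering property, the means of the published per-user Stroop
deviations; and two-Gaussian SCR classes at 0.68 V baseline, +50 mV stress
shift, 15 mV noise, n = 400 for threshold recovery (the paper-scale variant
uses a +22 mV shift at 5 mV noise, the separation of the published per-user
mean levels).

## Known limitations

* The published figure describing the coefficient pipeline and the chosen
  CWT scale are not recoverable from text; both are exposed as configurable
  strategies (`transform_coefficients()` strategy, `scale` argument) and the
  defaults above are this package's own calibration, not a fidelity claim.
* Amplitude banding assumes extrasystoles are attenuated at the analysis
  scale; morphology-based premature-beat classification is out of scope.
* The detector targets the low-noise wearable regime (see noise handling
  above); frequency-domain HRV, detrending and respiration correction are
  not provided.
* Tree induction implements gain-ratio splitting with optional
  reduced-error pruning only; confidence-factor (pessimistic) pruning of the
  original C4.5 is not reproduced.
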