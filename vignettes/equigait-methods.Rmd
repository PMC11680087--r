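---
title: "Methods: gait events, limb loads and asymmetry from body-worn IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait events, limb loads and asymmetry from body-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Sport horses distribute load laterally (left vs. right limbs) and
longitudinally (fore vs. hind), and both distributions shift with gait,
riding direction and training state. Force plates measure limb loads directly
but do not survive daily training conditions; small inertial measurement
units (IMUs) strapped laterally to the four cannon bones (plus one on the
saddle girth near the sternum) do. From five such 120 Hz recordings —
tri-axial accelerometer (g), gyroscope (deg/s) and optionally onboard-fused
Euler angles — `equigait` extracts, per limb and per stride:

* the gait-cycle boundaries and the hoof-on / hoof-off events,
* stride frequency, stance and swing durations and the duty factor
  (stance/stride),
* the peak impact limb load (PILL): the maximum of the tri-axial
  acceleration magnitude at hoof-on, in units of standard gravity
  (1 g = 9.81 m s⁻²), a surrogate for the compression load on the distal
  limb,

and per trial, the two normalised load-distribution indices

* longitudinal: `LongAI = (F − H) / ((F + H)/2) × 100 %`, positive when the
  forelimbs carry more load,
* lateral: `LatAI = (L − R) / ((L + R)/2) × 100 %`, computed separately
  within the fore and hind pairs, positive when the left limb carries more.

Both indices are antisymmetric in their arguments and bounded in
(−200, 200) by construction.

## Signal chain

**Magnitude.** All load measures use the Euclidean norm
√(aₓ² + a_y² + a_z²) of the accelerometer. The norm is invariant under any
rotation of the sensor's local frame, so the exact mounting orientation on
the boot is irrelevant; this is verified to 10⁻⁹ against random rotations in
the test suite.

**Filtering.** Peak picking operates on a second-order Butterworth low-pass
at 20 Hz. The filter is applied forward and backward (zero-phase): event
*timing* is the core output, and a causal filter would lag every event by a
gait-dependent amount. Because forward–backward filtering squares the
magnitude response, the effective attenuation at frequency f is
1/(1 + (f/20)⁴). Signals are padded by odd reflection at both ends before
filtering so that the filter state is settled at the edges; the first and
last 0.5 s of every trace are nevertheless excluded from event detection.
Whether the acceleration magnitude itself is filtered before peak picking is
configurable (`filter_acc`, default `TRUE`); the gyroscope trace used for
segmentation is always filtered.

**Pitch angle.** The cycle period is estimated from the oscillating pitch
angle — the inclination of the sensor x-axis (mounted along the cannon-bone
axis, positive upward) from the gravity-defined horizontal. If the recording
carries an orientation channel it is used directly; otherwise the gravity
direction is isolated with a 2 Hz low-pass per axis (stride content sits at
0.8–1.7 Hz and impact content far higher, but gravity is the DC component of
the *axis* signals, not of the magnitude) and pitch is
asin(aₓ,lp / |a|ₗₚ) — a resting sensor with its x-axis vertical reads +1 g
on x and +90°. Sustained (>0.25 s) loss of the gravity vector (|a|ₗₚ <
0.3 g) is an error, not a guess.

**Cycle period.** The dominant stride rhythm is the highest spectral peak of
the demeaned pitch trace in 0.4–2.5 Hz (covering walk to canter with
margin), on an FFT zero-padded 4× for resolution. If no peak exceeds 3× the
median in-band power the trace is rejected as "no gait".

**Segmentation.** The sagittal-plane angular velocity — the gyroscope
component about the mediolateral axis, i.e. `gyr_z` under the "z points
medially" mounting convention, negated on right limbs so protraction is
positive on both sides — shows one large lobe per swing phase. Peaks of the
filtered trace are picked with minimum separation 0.7× the period hint and
minimum prominence 0.3× the 95th-percentile amplitude (floored at 5% of the
maximum amplitude so numerically silent traces do not admit ripples).
Consecutive peaks delimit cycles, each beginning mid-swing. Cycles shorter
than 0.25 s are discarded as impossible at equine stride frequencies, and
cycles longer than 1.8× the period hint are discarded so that segments never
bridge silent gaps between movement bouts. Incomplete first/last cycles are
implicitly discarded because peaks delimit intervals.

**Event detection.** Within each cycle, impact candidates are local maxima
of the acceleration magnitude above max(2 g, cycle median + 4×MAD), at
least 50 ms apart. Hoof-on is the *first* candidate (initial ground
contact); hoof-off is the *most prominent* candidate after it. The "most
prominent after hoof-on" rule is this package's resolution of the ambiguity
that arises when mid-stance oscillations create additional peaks; it is
deliberate and configurable-free. Cycles with fewer than two candidates are
dropped and counted, and the drop counts are logged per trial. The same
two-peak logic is applied to walk, trot and canter, with the period hint
taken per limb (canter footfall spacing is asymmetric across limbs).

**PILL readout.** The 20 Hz filter attenuates a ~15 ms impact transient by
roughly 10%, so the load is never read off the detection trace. Instead,
windows of the *unfiltered* magnitude within ±25 ms of each detected hoof-on
are collected, re-centred on their local maximum, and — when at least five
strides are available — averaged after baseline removal and peak
normalisation into the trial's impact-pulse template; each stride's PILL is
then the least-squares projection of its window onto that template. This is
exact for noiseless pulses and averages down per-sample noise otherwise.
Inside the full pipeline the template is pooled across the four limbs of a
trial (impact transients share their shape across limbs): any error in the
template's amplitude anchoring then scales all limbs equally and cancels in
the asymmetry ratios. With fewer than five strides the window maximum is
used.

## From cycles to trial summaries

Stride duration is the cycle length; stance is hoof-off − hoof-on; swing is
the remainder, so stance + swing reconstructs the stride exactly; duty
factor is stance/stride; stride frequency is the inverse duration.
Aggregation is *limb means first, indices second*: per-limb means over
strides are formed, F and H are unweighted means of the two limb means in
each pair, and the indices are computed from those. One index per trial is
reported; mean-then-index is stable when limbs have unequal stride counts,
and no weighting is imposed. Trials with fewer than 3 strides on any limb
are rejected outright rather than imputed.

## Statistics

Cohort analyses operate on trial-summary tables. Gait- and
direction-dependent changes are tested with a within-subject
(repeated-measures) ANOVA: trial replicates are first averaged to one value
per horse and condition, the design must be complete and balanced, and the
univariate F tests are computed through a multivariate linear model (via
`car::Anova`). Mauchly's sphericity test is run whenever a factor has more
than two levels and the Greenhouse–Geisser-corrected p-value is reported
when Mauchly's p < 0.05 (the reported table carries both). Effect sizes are
partial η² = SS_effect/(SS_effect + SS_error) for the ANOVA and Cohen's d
(mean difference over pooled SD) for Tukey post hoc comparisons, which run
on a subject-blocked ANOVA of the cell means. Magnitude labels follow the
conventional bands (small/medium/large at |d| = 0.2/0.5/0.8). Assumption
checks — Shapiro–Wilk per group and Levene's test (mean-centred, the
original form) — are advisory only; the pipeline never switches tests
automatically. α is 0.05, two-sided, throughout. Rein direction is handled
as a second within-subject factor (the two-factor form); running separate
one-factor ANOVAs per rein is the documented alternative. Agreement between
two co-located sensor types is summarised by Pearson r, R², and Bland–Altman
mean difference with ±1.96 SD limits on hoof-on peak magnitudes matched by
nearest event time within 50 ms.

The suite verifies calibration rather than assuming it: the null rejection
rate of the RM-ANOVA over 2000 simulations must lie in [0.03, 0.07] at
α = 0.05, the two-condition F must equal the paired t² to 10⁻⁹, and partial
η² and d must match brute-force sums-of-squares oracles to 10⁻⁹.

## The synthetic gait simulator

No raw cohort recordings are publicly deposited, so every pipeline stage is
validated against a simulator whose defaults are reference cohort means for
ridden sport horses:
stride frequency 0.83/1.30/1.61 Hz, duty factor 0.629/0.407/0.419 (stance
duration × frequency), and PILL 6.55/9.77/14.03 g for walk/trot/canter.
Footfall templates: walk is four-beat with the lateral sequence LH, LF, RH,
RF at quarter-stride offsets; trot is two-beat with synchronous diagonal
pairs; canter is three-beat — trailing hind at phase 0, the diagonal pair at
0.30, leading fore at 0.45 — with the lead tied to the rein. The canter
phase values are simulator conventions, not claims about real horses. (Some
descriptions label walk as 3-beat; the simulator follows the four-beat
footfall sequence, which is the standard characterisation.)

Per limb, the acceleration magnitude is a 1 g baseline plus a Gaussian
impact pulse (σ = 15 ms — a single-parameter, peak-preserving transient) at
each hoof-on, peaking at the specified load, and a smaller pulse at each
hoof-off (default 0.55× the hoof-on peak, so that "second prominent peak"
detection is exercised non-trivially). Event times are quantised to the
120 Hz sampling grid so the imposed peaks are realised exactly in the
sampled signal. The tri-axial components place gravity and the pulses along
the sensor x-axis so the norm equals the target magnitude. The sagittal
angular velocity is one positive half-sine lobe per swing (negated on right
limbs), with one extra closing lobe after the last hoof-on so the final
stride's cycle can be delimited. The orientation channel carries a pitch
sinusoid at the stride frequency (10° amplitude about 60°); the trunk sensor
gets a vertical oscillation at twice the stride frequency in trot (diagonal
gait) and once per stride otherwise. White Gaussian noise is added per axis
(defaults 0.3 g and 15 deg/s — visible but modest relative to 6–14 g
impacts). Where a signal-to-noise ratio is quoted, it is the *power* SNR:
the time-averaged power of the noiseless magnitude above its 1 g baseline
divided by the per-axis noise variance; `noise_sd_for_snr()` converts.

Cohorts reproduce the study layout: 20 horses × 3 gaits × 4 trials
(~40 s each), balanced across rein, canter split into left-lead (left rein)
and right-lead (right rein). Horse-level LongAI offsets are drawn once per
horse (normal, SD 10%, around per-gait means of −6.24/−11.53/−0.72% for
walk/trot/canter) and LatAI offsets per pair (normal, SD 5%); they are
imposed exactly by scaling the per-limb impact peaks around the gait's mean
load, so the manifest's indices are exact ground truth. Everything is
reproducible from a single seed.

What the simulator does *not* emulate — and hence what passing tests do not
show about real data: soft-tissue and hoof-joint damping (real impact
transients are asymmetric and gait-dependent), stride-to-stride timing and
amplitude variability, curved-path and surface effects, drift or dropouts in
real sensors, and any correlation between PILL and stance duration. It
targets signal morphology sufficient to test the pipeline, nothing more.

## Numerical choices and degenerate inputs

* Unit auto-detection takes the norm of the per-axis medians as the resting
  (gravity) magnitude — robust to sparse impact transients and symmetric
  oscillations — and requires it to fall in [0.8, 1.2] (already g) or
  [8, 12] (m s⁻², divided by 9.81); anything else is a unit error, never a
  silent guess.
* Time is stored relative to the first sample; the median inter-sample
  interval must be within ±5% of the nominal rate, or the recording is
  rejected (gap detection).
* Constant signals: the period estimator raises a "no gait" error; the
  Spearman correlation raises an undefined-correlation error; the assumption
  checks raise a degenerate-input error.
* Tukey comparisons on literally identical conditions report d = 0 and
  adjusted p = 1 rather than 0/0.
* All detection thresholds are config-exposed defaults
  (`eqg_config()`/`--print-config`), and every threshold actually used is
  written to the run log.

## Problem sizes used in the tests

The suite validates event recovery on single 40 s trials per gait at power
SNR 10, asymmetry recovery on a 20-horse trot cohort with two 20 s trials
per horse, ANOVA calibration on 2000 null simulations of a 10-subject ×
3-condition design, and the acceptance script repeats these with 40 s
cohort trials. These sizes were chosen so the full suite exercises every
claim at cohort scale while remaining quick to run on a laptop.

## Known limitations

Hoof-off detection by "most prominent peak after hoof-on" can mistake a
strong mid-stance oscillation for lift-off in real data; the cycle-period
estimator assumes a single dominant rhythm and will fail on transitions
between gaits within a trial; the pipeline assumes hardware-side clock
synchronisation across sensors (a per-sensor constant offset can be applied
manually upstream); and no lameness grading or gait classification is
attempted — the package measures, it does not diagnose.
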