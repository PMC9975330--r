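---
title: "Quantifying hindlimb locomotor recovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hindlimb locomotor recovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locokit)
```

`locokit` quantifies locomotor function of the rodent hindlimb after
incomplete spinal cord injury from four kinds of recordings: sagittal
joint-marker kinematics (treadmill and swimming), hindlimb EMG,
photostimulation sessions probing descending motor efficacy, and
overhead open-field tracking. This vignette explains the models and
procedures, the parameters that matter, the synthetic-data generators
the test-suite runs on, and the numerical and design choices that were
genuinely open.

## Kinematics

**Coordinates.** Everything lives in the sagittal plane: x
rostral-positive, y dorsal-positive, units cm, time in seconds, all
intervals half-open `[start, end)`. Marker sets carry the iliac crest,
hip, ankle and toe; the knee is optional.

**Knee triangulation.** Skin slippage makes a tracked knee marker
unreliable, so the knee is placed at the intersection of two circles:
radius femur around the hip, radius tibia around the ankle
(`infer_knee()`). Two intersections exist; the default takes the one
rostral to the hip-ankle chord, where the mouse knee lies. When marker
noise stretches the chain beyond `femur + tibia` (or compresses it
below their difference) the circles do not intersect; rather than fail
mid-recording, the knee is projected onto the chord with the two
distances rescaled proportionally and the frame flagged `degraded`.
Joint angles are included angles at each joint: hip between the rays
toward iliac crest and knee, knee between hip and ankle, ankle between
knee and toe. Marker gaps of at most 4 frames (16 ms at 250 frames/s)
are filled by linear interpolation; longer gaps flag the frame missing
and exclude the affected cycles.

**Gait events.** Foot contact and lift-off are ideally tagged manually
(`read_gait_events()` accepts such files and they take precedence).
The automatic detector thresholds toe height at the 10th percentile of
toe height plus 0.1 cm, requiring contact runs of at least 20 ms. The
percentile anchor adapts to the ground level of each recording; the
0.1-cm margin covers marker-center offset and tracking noise.

**Cycle normalization and variability.** Cycles are anchored stance
onset to stance onset and linearly time-warped onto 512 bins, giving
per-joint cycle-by-bin matrices from which per-bin mean, SD and
coefficient of variation (CV = SD/|mean|) are computed. The swing
window runs from the maximal opening of the hip angle (the beginning
of swing under this cycle anchor) to the end of the cycle (foot
contact), so the CV window ends at the final bin. The swing-start bin
is located on the *across-cycle mean* hip profile by default: a common
window makes per-bin CVs comparable across cycles. A per-cycle variant
(`swing_from = "cycle"`, median of per-cycle argmaxima) is exposed
because either reading is defensible; the default is the stabler one.
Pooled swing-bin CVs are treated as a parameter sample and compared
across conditions by the statistical policy.

**Phase coupling.** Intralimb coupling is the per-cycle lag of the
ankle-angle maximum behind the hip-angle maximum, expressed as a cycle
fraction modulo 1; interlimb coupling is the cycle fraction at which
the other limb's stance onset falls within the reference limb's cycle
(stance onsets are used because only one limb carries markers).
Per-cycle phases are summarized by the circular mean and resultant
length R = |mean of exp(2*pi*i*phase)|; R is 1 iff all phases agree and
tends to 0 for uniform phases. Cycles with a flat angle trace (no
unique maximum) or without an other-limb event are skipped and
counted.

**Swim strokes.** The swim cycle is split at the extrema of the
smoothed hip angle: power stroke from a minimum to the next maximum,
return stroke from a maximum to the next minimum. Extrema come from an
alternating turning-point scan with a 2-degree prominence requirement
(smoothing: 5-frame moving average at 250 frames/s) — both constants
are this package's own defaults, chosen to suppress tracking noise
without losing genuine strokes, and both are configurable. Endpoint
convention: a stroke may *start* at the trace start (the leading
partial rise into the first detected maximum is a power stroke) but
must *end* at a detected extremum; a trailing segment that never
reaches its extremum is discarded. Swim frequency is estimated from
the spacing of same-type extrema, `(n_max - 1) / (t_last - t_first)`,
which is exact for periodic input and robust to the endpoint
convention. The "power stroke" magnitude is reported as the stroke's
angular amplitude (max minus min), an interpretation the data cannot
disambiguate further from a single hip angle.

**Gait metrics.** Stride length is the absolute toe advance between
consecutive stance onsets; step height the peak toe height during
swing minus mean toe height during the preceding stance; angular
excursion the per-cycle max minus min of each joint angle. Iliac-crest
height (a posture proxy) can be normalized to its mean over a
pre-stimulation baseline window.

## EMG

Signals are nominally 10 kHz, band-limited hardware-side; analysis
applies a zero-phase high-pass (4th-order Butterworth design run
forward and backward via `signal::filtfilt`) at 100 Hz before
rectification. The cutoff is a package default — the recording chain
fixes only "high-pass" — and is configurable (`highpass_hz`, `NULL`
disables).

**Motor spikes.** The detection threshold is 5 times the mean of the
rectified trace over an annotated rest interval (at least 0.5 s). A
spike is the onset of a supra-threshold excursion; crossings within a
2-ms dead time merge into the previous spike, and the amplitude is the
peak rectified value within the dead-time window. The dead time
separates successive motor-unit potentials at 10 kHz without gluing
whole bursts together. For a Gaussian noise floor the rest mean is
sigma*sqrt(2/pi), so the threshold sits near 4 noise SDs: rare tail
crossings (about 1e-4 per sample) are then unavoidable at any
signal-to-noise ratio. This matters only for very long recordings and
is the reason the synthetic generator defaults to a bounded noise
floor (below).

**Bursts and cycles.** Spike density is the Gaussian-kernel-smoothed
spike rate (SD 20 ms, evaluated at 1 kHz). A burst opens when density
rises above 0.5x the trace-wide mean of the nonzero density and closes
below 0.25x (hysteresis); bursts under 30 ms are discarded. These
constants are declared defaults, not inferred from any recording, and
manually selected bursts (`manual_bursts()`) override them — mirroring
practice, where burst selection is often manual. Step cycles are
anchored on the flexor (tibialis anterior): cycle k spans flexor onset
k to onset k+1, divided into 5 equal epochs, epochs 1–2 flexor-active
(swing), 3–5 extensor-active (stance). Burst *duration* and
*integrated amplitude* (integral of the rectified filtered trace over
the burst window, not the sum of spike amplitudes) are the per-burst
metrics. Note that density-based burst edges are widened by roughly
the kernel SD; overlap-based co-activation measures computed from
detected (rather than manually tagged) bursts inherit a small upward
bias.

## Evoked responses

Motor efficacy is probed with 10-ms light pulses during locomotion.
For each pulse, spikes are counted in a 50-ms window before pulse
onset and a 50-ms window after pulse *offset* — starting the post
window at onset + 10 ms keeps the windows equal length and excludes
the stimulation artifact interval; the alternative (post window at
onset) is not distinguishable from the procedure's wording and this
choice is flagged here. The response is excitatory if the count rises,
inhibitory if it falls, failure if unchanged; with integer counts in
50-ms windows "unchanged" is an exact zero difference by default
(`tolerance = 0`, exposed because no explicit criterion exists).
Classification is defined on density only; amplitude changes are
reported alongside but do not enter the label. Pulses are assigned to
the epoch (and hence swing/stance phase) containing them;
classification applies to the single-pulse protocol (pulses every 3 s,
150 per session) — train pulses at 20/50 Hz have colliding windows and
are excluded. Session summaries report per muscle x phase label
proportions; correlations of response metrics against the 20-point
locomotor score use ordinary least squares with Pearson r, and a
Spearman rank correlation alongside, since the original fits are not
named.

## Open field

The neck marker is tracked at 100 frames/s around a 1-s stimulation
train. Displacement is net (straight-line from the position at
stimulation onset), matching the bout criterion: a locomotor bout is a
displacement exceeding the 10-cm circle within a 3-s horizon, the
latency its first crossing, and `initiated_within_stim` flags
latencies within the train. Speed profiles are path length per 100-ms
bin after a 5-frame moving-average smoothing. The heading vector is
the net displacement over the first 500 ms of stimulation. Trials
classify as `straight_locomotion` (bout plus a heading displacement of
at least 5 cm), `rotation` (movement that stays confined within the
5-cm radius — the displacement-based reading of body rotation without
displacement; true head angle cannot be estimated from one marker), or
`no_response`. Movement means the smoothed maximal displacement
exceeds both a tracking-noise floor (3x the jitter SD, estimated from
the residual of raw around smoothed positions over the 1 s before
stimulation) and an absolute minimum of 1 cm; the absolute term is
needed because the maximum of a few hundred smoothed-noise
displacements concentrates near, not below, a pure 3-sigma floor. The
minimum movement separating rotation from no response is this
package's own rule — the original operational definition is not
quantified.

## Statistical decision policy

Every comparison is gated by Shapiro-Wilk normality at alpha = 0.05:
all groups must pass for the parametric branch (the conservative
reading when groups disagree; zero-variance groups route nonparametric
with a warning). Two groups: unpaired t test vs Mann-Whitney, paired t
vs Wilcoxon signed-rank. More than two: one-way ANOVA with Tukey (or
Dunnett-vs-first, both exposed because usage varies across analyses)
against Kruskal-Wallis with Dunn's post-hoc; paired designs use
repeated-measures one-way ANOVA with Tukey contrasts against Friedman
with Dunn's post-hoc. Dunn's tests are implemented in-package
(standard rank-sum z statistics with Bonferroni adjustment). Alpha is
0.05 throughout with no correction across mice or metrics, matching
per-subject reporting practice; a Holm option exists but is off by
default. `classify_change()` maps a significant change onto functional
semantics: a change in the gain direction (increase for excursion,
stride length, step height, speed, burst amplitude; *decrease* for
burst duration and swing CV) is an improvement, the opposite a
deficit, non-significance no change — these feed the
"percentage of animals improved/deteriorated" cohort summaries
(`aggregate_changes()`).

Calibration: under Gaussian and exponential two-sample nulls the gated
policy holds the 5% level (the acceptance checks measure both at 2000
replicates).

## Synthetic data: what it emulates and what it does not

All tests run on seeded generators that serialize every programmed
quantity alongside the data.

`gen_gait()` has two construction modes sharing one parameter set,
because no single construction can pin both ground-contact realism and
exact angle timing:

* **contact** (default): the toe is planted during stance and swings
  forward with a flat-topped lift; the hip advances at the mean
  progression speed (4-cm stride, 0.4-s cycles, duty factor 0.6 — a
  comfortable 10 cm/s walk); the knee follows by triangulation. Joint
  angles are emergent. Use it for event detection, duty factor, stride
  length, step height.
* **template**: joint angles are cosine templates with programmed peak
  phases (hip peaks at the stance-to-swing transition; knee and ankle
  lag by 0.15 and 0.25 cycles) scaled per cycle by `1 + e`; markers
  follow by forward kinematics. Use it for coupling and variability.
  Jitter draws are standardized so the realized per-cycle scale SD
  equals the programmed value exactly — parameter recovery is then a
  sharp test rather than a test of the draw.

`gen_emg()` renders spikes as 1-ms biphasic waveforms on a noise
floor, a quiet rest interval first. Locomotion sessions gate spikes by
alternating flexor/extensor envelopes (with optional co-activation
overlap); stimulation sessions use a tonic background process so
programmed per-pulse effects are always realizable — excitatory
pulses insert spikes into the largest free gaps of the post window,
inhibitory pulses thin spikes from it (pre-window statistics
untouched), failures do nothing. The default noise floor is bounded
(uniform): with the 5x-rest-mean threshold at about 4 Gaussian SDs, a
Gaussian floor would contribute rare spurious detections on long
records no matter the SNR, which would make exact-recovery guarantees
false for reasons unrelated to the code under test. Gaussian noise
remains available and is used where approximate recovery is asserted.

`gen_openfield()` draws trials as straight bouts (programmed latency,
heading, speed), confined rotation loops (2-cm radius, within the 5-cm
circle), or stationary jitter. `gen_swim()` produces hip-angle
oscillations with per-cycle duration jitter.

What the generators do **not** emulate — and what passing tests
therefore do not establish about real data: markerless-pose and
tracking artifacts beyond i.i.d. jitter (no occlusions, swaps or
autocorrelated drift), skin slippage, electrode drift and movement
artifact in EMG, motor-unit waveform variability and superposition at
high rates, behavioral nonstationarity (speed changes, stops,
arena-border effects), and any coupling between kinematics and EMG
beyond shared cycle timing. Recovery results certify the estimators'
correctness under the stated model, not robustness to everything real
recordings contain.

## Numerical choices

* Half-open cycle membership uses a 1-nanosecond tolerance so
  floating-point drift in cumulated event times cannot migrate
  boundary frames between cycles.
* CV bins with zero mean are flagged undefined and dropped from
  pooling rather than propagating infinities.
* Ties and degenerate cases: flat angle cycles are skipped and
  counted; wilcox tests run with `exact = FALSE`; epoch boundaries are
  computed as `start + duration * (0:5)/5` so the five epochs tile the
  cycle to machine precision.
* Problem sizes in the routine checks (1000 triangulation poses,
  50 oracle traces, 20-cycle ensembles, 150-pulse sessions, 2000-replicate
  calibration) were chosen as the smallest sizes at which the
  quantities of interest are estimated sharply.

## Known limitations

* Automatic gait events need a clear toe-height contact plateau;
  dragging gaits (early after injury) may require manual tagging, as
  in practice.
* Burst-edge widening by the density kernel biases detected burst
  durations upward by ~20-40 ms; comparisons between conditions are
  unaffected, absolute durations should use manual bursts.
* The rotation/no-response boundary (1-cm minimum movement) is a
  package convention; sessions with very large tracking noise should
  raise it.
* Interlimb coupling is defined on stance onsets only; it cannot
  distinguish phase lead from lag conventions beyond the cycle
  anchor chosen.
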