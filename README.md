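# locokit

Quantitative analysis of rodent hindlimb locomotion and its recovery
after incomplete spinal cord injury. `locokit` is aimed at motor-control
and SCI labs that record treadmill/swimming kinematics with reflective
joint markers, hindlimb EMG, optogenetic stimulation sessions, and
overhead open-field tracking — and want the full analysis chain, from
raw marker tables to the per-animal improvement/deficit verdicts, as
tested, scriptable R functions.

## What it computes

**Kinematics.** Joint markers (iliac crest, hip, ankle, toe; 250
frames/s) become included joint angles, with the knee inferred by
triangulation from femur and tibia lengths: the knee is the circle–circle
intersection `|K − H| = f`, `|K − A| = t` on the rostral side of the
hip–ankle chord. Gait cycles (stance onset → stance onset) are
time-normalized onto 512 bins; per-bin mean, SD and coefficient of
variation CV_b = SD_b/|mean_b| quantify step-to-step variability, pooled
over the swing window (maximal hip opening → foot contact). Intralimb
coordination is circular: per cycle, the phase φ = ((t_max_ankle −
t_max_hip)/T) mod 1, summarized by the circular mean and resultant
R = |⟨e^{2πiφ}⟩|. Swim cycles split into power (hip min → max) and
return (max → min) strokes. Per-cycle gait metrics: stride length, step
height, angular excursions, iliac-crest height (posture), step
frequency.

**EMG.** Motor spikes are threshold crossings of the rectified,
high-pass-filtered trace at 5× the mean rectified rest signal, with a
2-ms dead time. Spike density (Gaussian kernel, σ = 20 ms) segments
bursts with hysteresis; flexor (tibialis anterior) burst onsets anchor
step cycles, each divided into 5 equal epochs (1–2 swing, 3–5 stance).
Burst duration and integrated amplitude (∫|EMG| dt over the burst) are
the per-burst metrics.

**Evoked responses.** For each 10-ms light pulse, spike counts in 50-ms
windows before pulse onset and after pulse offset classify the response:
excitatory (count up), inhibitory (count down), failure (unchanged),
stratified by muscle and swing/stance phase, with proportions
correlated against the 20-point locomotor score.

**Open field.** From the neck-marker trajectory: 100-ms-bin speed
profiles; locomotor-bout detection (net displacement > 10 cm within 3 s
of stimulation onset, latency = first crossing); heading vectors over
the first 500 ms; trial classification as straight locomotion, rotation
(movement confined within a 5-cm radius) or no response.

**Statistics.** Every comparison is gated by Shapiro–Wilk normality:
t test vs Mann–Whitney (paired t / Wilcoxon when paired), ANOVA +
Tukey/Dunnett vs Kruskal–Wallis + Dunn, RM-ANOVA + Tukey vs Friedman +
Dunn. `classify_change()` turns significant per-animal changes into
improvement / deficit / no-change verdicts; `aggregate_changes()` builds
the cohort percentages.

**Synthetic data.** Seeded generators (`gen_gait`, `gen_emg`,
`gen_swim`, `gen_openfield`) produce marker tracks, EMG with programmed
evoked effects, swim traces and open-field trials with full ground
truth, so every stage is testable without any recordings.

## Worked example

A synthetic treadmill session with 8% per-cycle scale jitter, and an
EMG session, analyzed end to end:

```r
library(locokit)

g <- gen_gait(n_cycles = 20, mode = "template", swing_jitter_sd = 0.08,
              seed = 7)
ens <- normalize_cycles(g$angles, g$events)
ens
#> <cycle_ensemble> 20 cycles x 512 bins (0 rejected), swing from bin 308
mean(swing_cv(ens, "hip")$pooled)
#> [1] 0.08
intralimb_coupling(g$angles, g$events)
#> <phase_coupling> n = 20 cycles (0 skipped): mean phase 0.250, R = 1.000

em <- gen_emg(n_cycles = 15, seed = 8)
thr <- estimate_threshold(em$record, "LTA")   # 5 x rectified rest mean
signif(thr, 3)
#> [1] 0.0431
tr <- extract_spikes(em$record, "LTA", thr)
tr
#> <spike_train> LTA: 293 spikes (threshold 0.0431 mV)
bs <- detect_bursts(tr, record = em$record)
head(bs$bursts[, 1:4], 3)
#>   onset_s offset_s duration_s integrated_amplitude
#> 1   0.987    1.179      0.192           0.01515898
#> 2   1.387    1.590      0.203           0.01460243
#> 3   1.794    1.984      0.190           0.01396761
```

Reading of the numbers: the 20 normalized cycles place swing onset at
bin 308 of 512 (60% of the cycle — the programmed duty factor); the
pooled swing-phase CV of 0.08 recovers the programmed 8% cycle-scale
jitter; the ankle lags the hip by exactly the programmed quarter cycle
with perfect phase concentration (R = 1). The EMG threshold lands at
5× the rest floor, all rendered flexor spikes are recovered, and one
~0.2-s flexor burst is found per step cycle (2.5 Hz stepping).

`run_session()` orchestrates all stages from a manifest of inputs and
writes deterministic TSV/JSON reports via `write_report()`.

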