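#' Synthetic gait session with ground truth
#'
#' Generates a marker series, gait events and joint-angle ground truth
#' for a walking hindlimb at 250 frames/s, with every programmed
#' quantity recorded in `$truth`. Two construction modes are available:
#'
#' * `"contact"` (default): the limb is built from a ground-contact toe
#'   trajectory — the toe is planted during stance and swings forward
#'   with a flat-topped lift — and the hip advances at the mean
#'   progression speed; the knee follows by triangulation. Joint angles
#'   are emergent. This mode has realistic toe height, so contact-based
#'   event detection, duty factor, stride length and step height can be
#'   recovered from the markers.
#' * `"template"`: joint angles are built directly from cosine
#'   templates with programmed peak phases (the hip peaks at the
#'   stance-to-swing transition; knee and ankle lag it by the
#'   `phase_lags`), scaled per cycle by `1 + e` with
#'   `e ~ N(0, swing_jitter_sd)` (the whole-cycle scale that sets the
#'   swing-phase CV), and markers follow by forward kinematics from a
#'   fixed hip. This mode gives exact control of coupling phases and
#'   variability; its toe height is not contact-like, so events come
#'   from the returned ground truth.
#'
#' @param n_cycles number of step cycles.
#' @param cycle_duration_s mean cycle duration (0.4 s, i.e. 2.5 Hz
#'   stepping at a comfortable treadmill speed).
#' @param stance_fraction duty factor in (0, 1).
#' @param frame_rate frames per second.
#' @param stride_length_cm,step_height_cm contact-mode toe program.
#' @param segs hindlimb [segment_lengths()].
#' @param hip_height_cm hip height above ground, cm.
#' @param foot_cm ankle-to-toe segment, cm.
#' @param templates template-mode angle templates: named list
#'   `hip/knee/ankle`, each `c(mean, amplitude)` in degrees.
#' @param phase_lags template-mode peak lags (cycle fractions) of knee
#'   and ankle behind the hip peak.
#' @param ankle_lag_jitter_sd per-cycle circular jitter (cycle
#'   fractions) of the ankle lag, template mode.
#' @param swing_jitter_sd SD of the per-cycle template scale factor.
#' @param cycle_jitter_sd SD of the relative cycle-duration jitter.
#' @param marker_noise_sd_cm isotropic Gaussian marker noise.
#' @param mode `"contact"` or `"template"`.
#' @param include_knee include the knee marker in the output series.
#' @param seed RNG seed, recorded in the truth block.
#' @return list of class `gait_sim`: `markers` ([marker_series()]),
#'   `events` (ground-truth [gait_events()]), `angles` (noiseless
#'   `joint_angles`), and `truth`.
#' @export
gen_gait <- function(n_cycles = 10, cycle_duration_s = 0.4,
                     stance_fraction = 0.6, frame_rate = 250,
                     stride_length_cm = 4, step_height_cm = 0.8,
                     segs = segment_lengths(1.55, 1.85),
                     hip_height_cm = 2.6, foot_cm = 0.9,
                     templates = list(hip = c(110, 20), knee = c(90, 25),
                                      ankle = c(95, 30)),
                     phase_lags = c(knee = 0.15, ankle = 0.25),
                     ankle_lag_jitter_sd = 0,
                     swing_jitter_sd = 0, cycle_jitter_sd = 0,
                     marker_noise_sd_cm = 0,
                     mode = c("contact", "template"),
                     include_knee = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 1, stance_fraction > 0, stance_fraction < 1,
            cycle_duration_s > 0, frame_rate > 0)
  set.seed(seed)
  durs <- cycle_duration_s *
    pmax(0.5, 1 + stats::rnorm(n_cycles, 0, cycle_jitter_sd))
  onsets <- cumsum(c(0, durs))
  # include the closing foot contact so all n_cycles cycles are complete
  stance_onsets <- onsets
  swing_onsets <- onsets[seq_len(n_cycles)] + stance_fraction * durs
  total <- onsets[n_cycles + 1]
  t <- seq(0, total + 1e-9, by = 1 / frame_rate)  # span includes the
  # closing foot contact; tolerance keeps boundary frames in their own
  # cycle despite
  # floating-point drift in the cumulative onset times
  cyc_of <- findInterval(t + 1e-9, onsets, rightmost.closed = FALSE)
  cyc_of <- pmin(cyc_of, n_cycles)
  tau <- t - onsets[cyc_of]
  phi <- tau / durs[cyc_of]

  if (mode == "contact") {
    beta <- stance_fraction
    S <- stride_length_cm; h <- step_height_cm
    foot_dir <- c(cos(125 * pi / 180), sin(125 * pi / 180))
    in_stance <- phi < beta
    u <- pmax(0, (phi - beta) / (1 - beta))
    footfall_x <- (cyc_of - 1) * S
    toe_x <- ifelse(in_stance, footfall_x,
                    footfall_x + S * (1 - cos(pi * u)) / 2)
    toe_y <- ifelse(in_stance, 0, h * pmin(1, 3 * sin(pi * u)))
    hip_x <- footfall_x + phi * S - S * beta / 2
    hip_y <- rep(hip_height_cm, length(t))
    ankle_x <- toe_x + foot_cm * foot_dir[1]
    ankle_y <- toe_y + foot_cm * foot_dir[2]
    tri <- triangulate_knee(cbind(hip_x, hip_y), cbind(ankle_x, ankle_y),
                            segs, side = "rostral")
    if (any(tri$invalid) || any(tri$degraded)) {
      stop("impossible geometry: hip-ankle distance incompatible with segment lengths")
    }
    knee_x <- tri$knee[, 1]; knee_y <- tri$knee[, 2]
    iliac_x <- hip_x + 1.2 * cos(pi / 3)
    iliac_y <- hip_y + 1.2 * sin(pi / 3)
    coords <- data.frame(iliac_crest_x = iliac_x, iliac_crest_y = iliac_y,
                         hip_x = hip_x, hip_y = hip_y,
                         knee_x = knee_x, knee_y = knee_y,
                         ankle_x = ankle_x, ankle_y = ankle_y,
                         toe_x = toe_x, toe_y = toe_y)
    truth_extra <- list()
  } else {
    # jitter draws are standardized so the realized per-cycle scale SD
    # equals the programmed value exactly (fixed empirical moments)
    std_noise <- function(n, sd) {
      if (sd == 0 || n < 2L) return(numeric(n))
      e <- stats::rnorm(n)
      (e - mean(e)) / stats::sd(e) * sd
    }
    scale_c <- 1 + std_noise(n_cycles, swing_jitter_sd)
    lag_ankle_c <- phase_lags[["ankle"]] +
      std_noise(n_cycles, ankle_lag_jitter_sd)
    peak <- list(hip = rep(stance_fraction, n_cycles),
                 knee = rep(stance_fraction + phase_lags[["knee"]], n_cycles),
                 ankle = stance_fraction + lag_ankle_c)
    ang <- lapply(c("hip", "knee", "ankle"), function(j) {
      tpl <- templates[[j]]
      (tpl[1] + tpl[2] * cos(2 * pi * (phi - peak[[j]][cyc_of]))) *
        scale_c[cyc_of]
    })
    names(ang) <- c("hip", "knee", "ankle")
    lim <- range(unlist(ang))
    if (lim[1] <= 0 || lim[2] >= 180) {
      stop("impossible geometry: template angles leave (0, 180) degrees")
    }
    coords <- pose_markers(ang$hip, ang$knee, ang$ankle, segs,
                           hip_pos = c(0, hip_height_cm),
                           foot_cm = foot_cm)
    truth_extra <- list(scale = scale_c, ankle_lag = lag_ankle_c,
                        templates = templates, phase_lags = phase_lags)
  }

  angles_truth <- compute_joint_angles(
    marker_series(coords, frame_rate, time_s = t), segs = segs)
  if (marker_noise_sd_cm > 0) {
    for (nm in names(coords)) {
      coords[[nm]] <- coords[[nm]] +
        stats::rnorm(nrow(coords), 0, marker_noise_sd_cm)
    }
  }
  if (!include_knee) coords$knee_x <- coords$knee_y <- NULL
  markers <- marker_series(coords, frame_rate, time_s = t)
  events <- gait_events(stance_onsets, swing_onsets, source = "manual")
  structure(list(
    markers = markers, events = events, angles = angles_truth,
    truth = c(list(seed = seed, mode = mode, n_cycles = n_cycles,
                   cycle_durations_s = durs,
                   stance_onsets = stance_onsets,
                   swing_onsets = swing_onsets,
                   stance_fraction = stance_fraction,
                   stride_length_cm = stride_length_cm,
                   step_height_cm = step_height_cm),
              truth_extra)
  ), class = "gait_sim")
}

#' Synthetic swim hip-angle trace
#'
#' Sinusoid-like hip angle with per-cycle duration jitter: each cycle
#' runs minimum-to-minimum (power stroke then return stroke).
#'
#' @param frequency_hz programmed mean stroke frequency (> 0).
#' @param n_cycles number of full swim cycles.
#' @param jitter_sd SD of the relative cycle-duration jitter.
#' @param mean_deg,amp_deg hip-angle offset and half-amplitude.
#' @param frame_rate frames per second.
#' @param seed RNG seed.
#' @return list of class `swim_sim`: `hip_deg`, `time_s`, `frame_rate`,
#'   `truth`.
#' @export
gen_swim <- function(frequency_hz = 4, n_cycles = 20, jitter_sd = 0,
                     mean_deg = 100, amp_deg = 25, frame_rate = 250,
                     seed = 1L) {
  stopifnot(frequency_hz > 0, n_cycles >= 1)
  set.seed(seed)
  durs <- (1 / frequency_hz) *
    pmax(0.5, 1 + stats::rnorm(n_cycles, 0, jitter_sd))
  bounds <- cumsum(c(0, durs))
  total <- bounds[n_cycles + 1]
  t <- seq(0, total - 1 / frame_rate, by = 1 / frame_rate)
  k <- pmin(findInterval(t, bounds), n_cycles)
  s <- (t - bounds[k]) / durs[k]
  hip <- mean_deg - amp_deg * cos(2 * pi * s)
  list(hip_deg = hip, time_s = t, frame_rate = frame_rate,
       truth = list(seed = seed, frequency_hz = frequency_hz,
                    n_cycles = n_cycles, cycle_durations_s = durs,
                    realized_frequency_hz = n_cycles / total))
}

# 1-ms biphasic spike waveform, peak-normalized to 1.
spike_waveform <- function(sample_rate) {
  n <- max(4L, as.integer(round(0.001 * sample_rate)))
  w <- sin(2 * pi * (seq_len(n) - 1) / n)
  w / max(abs(w))
}

#' Synthetic EMG session with ground truth
#'
#' Renders multichannel EMG at 10 kHz: amplitude-marked motor spikes
#' (1-ms biphasic waveforms) on a noise floor, preceded by a quiet rest
#' interval. Two session types:
#'
#' * locomotion (`stim = NULL`): spikes are gated by alternating burst
#'   envelopes — the flexor (TA) active over the first
#'   `flexor_fraction` of each cycle, the extensor (GL) over the rest,
#'   with optional co-activation overlap.
#' * stimulation (`stim` given): a tonic background spike process with
#'   programmed per-pulse effects injected in the 50-ms post-pulse
#'   window — `effect_size` spikes added (excitatory), removed by
#'   thinning (inhibitory), or nothing (failure). Thinning and
#'   insertion leave the pre-pulse window untouched. With `spacing =
#'   "regular"` and `noise = "uniform"` the rendering is deterministic
#'   in the sense that detected counts equal programmed counts exactly
#'   (uniform noise never reaches the 5x-rest-mean threshold).
#'
#' @param n_cycles,cycle_duration_s,flexor_fraction locomotion-session
#'   cycle program (2.5 Hz stepping by default).
#' @param coactivation_fraction fraction of the flexor burst overlapped
#'   by the extensor burst (0 = strict alternation).
#' @param channels channel names to render; the first is the flexor
#'   reference (TA), the second the extensor (GL).
#' @param burst_rate_hz in-burst spike rate.
#' @param amp_mean_mV,amp_sd_mV spike amplitude distribution.
#' @param noise_sd_mV noise-floor scale (SD for Gaussian, half-width
#'   matched SD for uniform).
#' @param noise `"uniform"` (bounded, ADC-like floor; the default under
#'   which threshold crossings are spike-only), `"gaussian"`, or `"none"`.
#' @param spacing `"poisson"` (thinned to `min_isi_s`) or `"regular"`.
#' @param min_isi_s minimum inter-spike interval.
#' @param rest_s length of the quiet rest interval at the record start.
#' @param sample_rate samples per second.
#' @param stim `NULL`, or a list with `n_pulses` (150 single pulses by
#'   default), `period_s` (3 s), `pulse_duration_s` (0.010),
#'   `effect_size` (spikes added/removed, max 4), `background_rate_hz`
#'   (tonic rate, 100/s), and either `labels` (character vector) or
#'   `mixture` (named probabilities for excitatory / inhibitory /
#'   failure).
#' @param seed RNG seed.
#' @return list of class `emg_sim`: `record` ([emg_record()]),
#'   `protocol` ([stim_protocol()] or NULL), `truth` (per-channel spike
#'   times/amplitudes, burst windows, cycle bounds, per-pulse labels).
#' @export
gen_emg <- function(n_cycles = 20, cycle_duration_s = 0.4,
                    flexor_fraction = 0.4, coactivation_fraction = 0,
                    channels = c("LTA", "LGL"), burst_rate_hz = 200,
                    amp_mean_mV = 1, amp_sd_mV = 0.1,
                    noise_sd_mV = 0.01, noise = c("uniform", "gaussian", "none"),
                    spacing = c("poisson", "regular"), min_isi_s = 0.003,
                    rest_s = 1, sample_rate = 10000, stim = NULL,
                    seed = 1L) {
  noise <- match.arg(noise)
  spacing <- match.arg(spacing)
  set.seed(seed)

  draw_spikes <- function(win0, win1, rate) {
    if (win1 <= win0 || rate <= 0) return(numeric(0))
    if (spacing == "regular") {
      seq(win0 + min_isi_s / 2, win1 - 1e-9, by = 1 / rate)
    } else {
      n <- stats::rpois(1, rate * (win1 - win0) * 1.5)
      tt <- sort(stats::runif(n, win0, win1))
      keep <- c(TRUE, diff(tt) >= min_isi_s)
      tt <- tt[keep]
      if (length(tt) > rate * (win1 - win0)) {
        tt <- sort(sample(tt, round(rate * (win1 - win0))))
      }
      tt
    }
  }

  truth <- list(seed = seed)
  spikes <- list()
  if (is.null(stim)) {
    onsets <- rest_s + (seq_len(n_cycles) - 1) * cycle_duration_s
    flex_on <- onsets
    flex_off <- onsets + flexor_fraction * cycle_duration_s
    ext_on <- flex_off - coactivation_fraction * flexor_fraction * cycle_duration_s
    ext_off <- onsets + cycle_duration_s
    total <- rest_s + n_cycles * cycle_duration_s + 0.2
    for (i in seq_along(channels)) {
      ch <- channels[i]
      wins <- if (i %% 2L == 1L) cbind(flex_on, flex_off)
              else cbind(ext_on, ext_off)
      tt <- sort(unlist(lapply(seq_len(nrow(wins)), function(k) {
        draw_spikes(wins[k, 1], wins[k, 2], burst_rate_hz)
      })))
      spikes[[ch]] <- tt
    }
    truth$cycles <- data.frame(start_s = onsets,
                               end_s = onsets + cycle_duration_s)
    truth$flexor_bursts <- data.frame(onset_s = flex_on, offset_s = flex_off)
    truth$extensor_bursts <- data.frame(onset_s = ext_on, offset_s = ext_off)
    protocol <- NULL
  } else {
    n_pulses <- stim$n_pulses %||% 150
    period <- stim$period_s %||% 3
    pdur <- stim$pulse_duration_s %||% 0.010
    eff <- stim$effect_size %||% 2
    stopifnot(eff >= 1, eff <= 4)
    bg_rate <- stim$background_rate_hz %||% 100
    pulse_on <- rest_s + 1 + (seq_len(n_pulses) - 1) * period
    total <- rest_s + 1 + n_pulses * period
    labels <- stim$labels
    if (is.null(labels)) {
      mix <- stim$mixture %||% c(excitatory = 0.6, inhibitory = 0.25,
                                 failure = 0.15)
      stopifnot(abs(sum(mix) - 1) < 1e-9)
      labels <- sample(names(mix), n_pulses, replace = TRUE, prob = mix)
    }
    stopifnot(length(labels) == n_pulses)
    bg <- draw_spikes(rest_s + 0.005, total - 0.005, bg_rate)
    tt <- bg
    for (p in seq_len(n_pulses)) {
      w0 <- pulse_on[p] + pdur
      w1 <- w0 + 0.050
      if (labels[p] == "excitatory") {
        inwin <- sort(tt[tt >= w0 & tt < w1])
        anchors <- unique(sort(c(w0, inwin, w1)))
        mids <- (anchors[-1] + anchors[-length(anchors)]) / 2
        gapw <- diff(anchors)
        mids <- mids[order(-gapw)]
        tt <- c(tt, mids[seq_len(eff)])
      } else if (labels[p] == "inhibitory") {
        inwin <- which(tt >= w0 & tt < w1)
        if (length(inwin) < eff) stop("not enough background spikes to thin")
        tt <- tt[-inwin[seq_len(eff)]]
      }
    }
    tt <- sort(tt)
    spikes[[channels[1]]] <- tt
    if (length(channels) > 1L) {
      for (ch in channels[-1]) {
        spikes[[ch]] <- draw_spikes(rest_s + 0.005, total - 0.005, bg_rate)
      }
    }
    protocol <- stim_protocol(pulse_on, pulse_duration_s = pdur)
    truth$pulse_labels <- labels
    truth$pulse_onsets_s <- pulse_on
    truth$effect_size <- eff
  }

  n_samp <- as.integer(round(total * sample_rate))
  wf <- spike_waveform(sample_rate)
  traces <- list()
  amps <- list()
  for (ch in names(spikes)) {
    x <- switch(noise,
                gaussian = stats::rnorm(n_samp, 0, noise_sd_mV),
                uniform = stats::runif(n_samp, -noise_sd_mV * sqrt(3),
                                       noise_sd_mV * sqrt(3)),
                none = numeric(n_samp))
    a <- pmax(0.1, stats::rnorm(length(spikes[[ch]]), amp_mean_mV, amp_sd_mV))
    idx0 <- as.integer(round(spikes[[ch]] * sample_rate)) + 1L
    for (k in seq_along(idx0)) {
      j <- idx0[k]:min(n_samp, idx0[k] + length(wf) - 1L)
      x[j] <- x[j] + a[k] * wf[seq_along(j)]
    }
    traces[[ch]] <- x
    amps[[ch]] <- a
  }
  truth$spike_times <- spikes
  truth$spike_amps <- amps
  record <- emg_record(traces, sample_rate = sample_rate,
                       rest_interval = c(0, rest_s))
  structure(list(record = record, protocol = protocol, truth = truth),
            class = "emg_sim")
}

#' Synthetic open-field trajectories with ground truth
#'
#' Neck-marker trajectories at 100 frames/s around a 1-s stimulation
#' train: stationary tracking jitter before the programmed latency,
#' then per trial either a straight bout at the programmed heading and
#' speed, a confined rotation loop (movement without leaving the 5-cm
#' circle), or nothing.
#'
#' @param n_trials number of trials.
#' @param classes per-trial classes (`"straight"`, `"rotation"`,
#'   `"none"`), or `NULL` to draw from `mixture`.
#' @param mixture named class probabilities.
#' @param latency_s programmed movement-onset latency after stimulation
#'   onset.
#' @param speed_cm_s straight-bout speed.
#' @param heading_deg heading of straight bouts; `NULL` draws uniform.
#' @param rotation_radius_cm,rotation_speed_cm_s rotation-loop program.
#' @param jitter_sd_cm tracking-noise SD per coordinate.
#' @param pre_s,post_s seconds recorded before/after stimulation onset.
#' @param stim_duration_s train duration.
#' @param frame_rate frames per second.
#' @param seed RNG seed.
#' @return list of class `openfield_sim`: `trials` (list of
#'   [trajectory2d()]) and `truth` (per-trial class, latency, heading,
#'   speed).
#' @export
gen_openfield <- function(n_trials = 20, classes = NULL,
                          mixture = c(straight = 0.5, rotation = 0.25,
                                      none = 0.25),
                          latency_s = 0, speed_cm_s = 25,
                          heading_deg = NULL, rotation_radius_cm = 2,
                          rotation_speed_cm_s = 8, jitter_sd_cm = 0.05,
                          pre_s = 2, post_s = 4, stim_duration_s = 1,
                          frame_rate = 100, seed = 1L) {
  set.seed(seed)
  if (is.null(classes)) {
    stopifnot(abs(sum(mixture) - 1) < 1e-9)
    classes <- sample(names(mixture), n_trials, replace = TRUE,
                      prob = mixture)
  }
  stopifnot(length(classes) == n_trials)
  t <- seq(0, pre_s + post_s, by = 1 / frame_rate)
  trials <- vector("list", n_trials)
  headings <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    th <- if (is.null(heading_deg)) stats::runif(1, 0, 360)
          else rep_len(heading_deg, n_trials)[k]
    headings[k] <- th
    move_t <- pmax(0, t - pre_s - latency_s)
    if (classes[k] == "straight") {
      x <- speed_cm_s * move_t * cos(th * pi / 180)
      y <- speed_cm_s * move_t * sin(th * pi / 180)
    } else if (classes[k] == "rotation") {
      r <- rotation_radius_cm
      omega <- rotation_speed_cm_s / r
      cx <- r * cos(th * pi / 180); cy <- r * sin(th * pi / 180)
      a0 <- atan2(-cy, -cx)
      x <- cx + r * cos(a0 + omega * move_t)
      y <- cy + r * sin(a0 + omega * move_t)
    } else {
      x <- numeric(length(t)); y <- numeric(length(t))
    }
    if (jitter_sd_cm > 0) {
      x <- x + stats::rnorm(length(t), 0, jitter_sd_cm)
      y <- y + stats::rnorm(length(t), 0, jitter_sd_cm)
    }
    trials[[k]] <- trajectory2d(x, y, frame_rate = frame_rate,
                                stim_onset_s = pre_s,
                                stim_offset_s = pre_s + stim_duration_s,
                                time_s = t)
  }
  structure(list(trials = trials,
                 truth = list(seed = seed, classes = classes,
                              latency_s = latency_s,
                              speed_cm_s = speed_cm_s,
                              heading_deg = headings)),
            class = "openfield_sim")
}
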