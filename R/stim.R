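#' Photostimulation protocol
#'
#' Single 10-ms pulses delivered every few seconds probe motor efficacy
#' (response classification); 1-s trains at 5/10/20/50 Hz drive
#' behavior. Response classification is defined for the single-pulse
#' protocol; train pulses whose 50-ms windows collide are excluded.
#'
#' @param pulse_onsets_s increasing pulse onset times (s); for
#'   `mode = "train"` these may be generated from the train spec.
#' @param pulse_duration_s pulse width, 0.010 s by default.
#' @param mode `"single_pulses"` or `"train"`.
#' @param train_frequency_hz,train_duration_s train parameters (one of
#'   5/10/20/50 Hz, 1 s) when `mode = "train"`.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_onsets_s, pulse_duration_s = 0.010,
                          mode = c("single_pulses", "train"),
                          train_frequency_hz = NULL,
                          train_duration_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(pulse_onsets_s, strictly = TRUE),
            pulse_duration_s > 0)
  if (mode == "train") {
    stopifnot(train_frequency_hz %in% c(5, 10, 20, 50),
              isTRUE(train_duration_s > 0))
  }
  structure(list(pulse_onsets_s = as.numeric(pulse_onsets_s),
                 pulse_duration_s = pulse_duration_s, mode = mode,
                 train_frequency_hz = train_frequency_hz,
                 train_duration_s = train_duration_s),
            class = "stim_protocol")
}

#' Read a stimulation protocol from JSON
#'
#' Accepts either explicit `pulse_onsets_s` or a train spec
#' (`frequency_hz`, `duration_s`, `period_s`, `n_trains`,
#' `first_onset_s`) from which pulse onsets are expanded.
#'
#' @param path JSON file.
#' @return a [stim_protocol()].
#' @export
read_stim_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dur <- j$pulse_duration_s %||% 0.010
  if (!is.null(j$pulse_onsets_s)) {
    return(stim_protocol(j$pulse_onsets_s, pulse_duration_s = dur))
  }
  first <- j$first_onset_s %||% 0
  onsets <- as.vector(outer(seq(0, by = 1 / j$frequency_hz,
                                length.out = j$frequency_hz * j$duration_s),
                            first + (seq_len(j$n_trains) - 1) * j$period_s,
                            `+`))
  stim_protocol(sort(onsets), pulse_duration_s = dur, mode = "train",
                train_frequency_hz = j$frequency_hz,
                train_duration_s = j$duration_s)
}

#' Peristimulus spike counts and amplitudes
#'
#' Counts spikes in the 50-ms window before pulse onset and the 50-ms
#' window after pulse offset (the post window starts at onset + pulse
#' duration, excluding the stimulation artifact interval and keeping
#' the windows equal length). Windows are half-open.
#'
#' @param train a [spike_train()].
#' @param pulse_onset_s pulse onset time (s).
#' @param pulse_duration_s pulse width (s), 0.010 by default.
#' @param window_s window length (s), 0.050 by default.
#' @param record_span optional `c(start_s, end_s)`; a pulse whose
#'   windows extend past the span is marked excluded.
#' @return list with `pre_count`, `post_count`, `pre_mean_amp`,
#'   `post_mean_amp` (NA when no spikes), and `excluded`.
#' @export
pulse_window_counts <- function(train, pulse_onset_s,
                                pulse_duration_s = 0.010,
                                window_s = 0.050, record_span = NULL) {
  stopifnot(inherits(train, "spike_train"))
  pre0 <- pulse_onset_s - window_s
  post0 <- pulse_onset_s + pulse_duration_s
  post1 <- post0 + window_s
  excluded <- FALSE
  if (!is.null(record_span) &&
      (pre0 < record_span[1] || post1 > record_span[2])) {
    excluded <- TRUE
  }
  st <- train$spike_times_s; am <- train$amplitudes_mV
  pre <- st >= pre0 & st < pulse_onset_s
  post <- st >= post0 & st < post1
  list(pre_count = sum(pre), post_count = sum(post),
       pre_mean_amp = if (any(pre)) mean(am[pre]) else NA_real_,
       post_mean_amp = if (any(post)) mean(am[post]) else NA_real_,
       excluded = excluded)
}

#' Classify an evoked motor response
#'
#' The sign of the change in motor-spike count between the post- and
#' pre-pulse windows: excitatory when the count increases by more than
#' `tolerance`, inhibitory when it decreases by more than `tolerance`,
#' failure otherwise. With integer counts in 50-ms windows, the default
#' tolerance of 0 makes "absence of change" an exact zero difference.
#'
#' @param pre_count,post_count nonnegative spike counts (vectorized).
#' @param tolerance count difference treated as no change.
#' @return character vector in `c("excitatory", "inhibitory", "failure")`.
#' @export
classify_response <- function(pre_count, post_count, tolerance = 0) {
  stopifnot(all(pre_count >= 0), all(post_count >= 0))
  d <- post_count - pre_count
  ifelse(d > tolerance, "excitatory",
         ifelse(-d > tolerance, "inhibitory", "failure"))
}

#' Assign a pulse to its step-cycle epoch and phase
#'
#' @param pulse_onset_s pulse onset time (s).
#' @param partition an `epoch_partition` from [segment_cycles()].
#' @return list with `epoch` (1-5), `phase` (`"swing"` for epochs 1-2,
#'   `"stance"` for 3-5) and `cycle` index, or all-NA when the pulse
#'   falls outside every segmented cycle.
#' @export
assign_pulse_phase <- function(pulse_onset_s, partition) {
  stopifnot(inherits(partition, "epoch_partition"))
  cy <- partition$cycles
  k <- which(pulse_onset_s >= cy$start_s & pulse_onset_s < cy$end_s)
  if (length(k) == 0L) {
    return(list(epoch = NA_integer_, phase = NA_character_,
                cycle = NA_integer_))
  }
  k <- k[1]
  frac <- (pulse_onset_s - cy$start_s[k]) / (cy$end_s[k] - cy$start_s[k])
  epoch <- min(5L, floor(frac * 5) + 1L)
  list(epoch = epoch, phase = if (epoch <= 2L) "swing" else "stance",
       cycle = k)
}

#' Per-pulse response table for a session
#'
#' Convenience wrapper running [pulse_window_counts()],
#' [classify_response()] and [assign_pulse_phase()] over every pulse of
#' a protocol. Pulses with colliding windows (train mode at high
#' frequency) or windows outside the record span are excluded and
#' counted.
#'
#' @param train a [spike_train()].
#' @param protocol a [stim_protocol()].
#' @param partition optional `epoch_partition` for phase assignment.
#' @param record_span optional `c(start_s, end_s)` of the recording.
#' @param window_s peristimulus window length (s).
#' @param tolerance classification tolerance, see [classify_response()].
#' @return data frame with one row per pulse: counts, amplitudes,
#'   `delta_density` (post - pre counts per window), `label`, `epoch`,
#'   `phase`, `muscle`, `excluded`.
#' @export
pulse_responses <- function(train, protocol, partition = NULL,
                            record_span = NULL, window_s = 0.050,
                            tolerance = 0) {
  stopifnot(inherits(protocol, "stim_protocol"))
  on <- protocol$pulse_onsets_s
  dur <- protocol$pulse_duration_s
  # window collision: pre window of a pulse reaches into the previous
  # pulse's post window (or vice versa)
  min_gap <- dur + 2 * window_s
  collide <- rep(FALSE, length(on))
  if (length(on) > 1L) {
    gaps <- diff(on)
    collide <- c(gaps < min_gap, FALSE) | c(FALSE, gaps < min_gap)
  }
  rows <- lapply(seq_along(on), function(i) {
    w <- pulse_window_counts(train, on[i], pulse_duration_s = dur,
                             window_s = window_s, record_span = record_span)
    ph <- if (!is.null(partition)) assign_pulse_phase(on[i], partition)
          else list(epoch = NA_integer_, phase = NA_character_)
    data.frame(pulse_time_s = on[i],
               pre_count = w$pre_count, post_count = w$post_count,
               delta_density = w$post_count - w$pre_count,
               pre_mean_amp_mV = w$pre_mean_amp,
               post_mean_amp_mV = w$post_mean_amp,
               label = classify_response(w$pre_count, w$post_count,
                                         tolerance = tolerance),
               epoch = ph$epoch, phase = ph$phase %||% NA_character_,
               muscle = train$channel,
               excluded = w$excluded || collide[i] ||
                 (!is.null(partition) && is.na(ph$epoch)))
  })
  do.call(rbind, rows)
}

#' Summarize evoked responses per muscle and phase
#'
#' Label proportions (excitatory / inhibitory / failure, summing to 1)
#' and mean density and amplitude changes per label, within each muscle
#' x phase stratum of included pulses. Empty strata are omitted.
#'
#' @param responses a data frame from [pulse_responses()] (rows with
#'   `excluded = TRUE` are dropped), or a concatenation across muscles.
#' @return object of class `response_summary`: data frame `strata` with
#'   `muscle`, `phase`, `n_pulses`, `proportion_excitatory`,
#'   `proportion_inhibitory`, `proportion_failure`, and per-label mean
#'   `delta_density` / amplitude change columns.
#' @export
summarize_session <- function(responses) {
  stopifnot(is.data.frame(responses))
  inc <- responses[!responses$excluded, , drop = FALSE]
  if (nrow(inc) == 0L) stop("no included pulses")
  strat <- unique(inc[, c("muscle", "phase")])
  rows <- lapply(seq_len(nrow(strat)), function(i) {
    sel <- inc$muscle == strat$muscle[i] &
      (inc$phase == strat$phase[i] | (is.na(inc$phase) & is.na(strat$phase[i])))
    sel[is.na(sel)] <- FALSE
    s <- inc[sel, , drop = FALSE]
    n <- nrow(s)
    amp_change <- s$post_mean_amp_mV - s$pre_mean_amp_mV
    mean_by <- function(v, lab) {
      x <- v[s$label == lab]
      if (length(x) == 0L) NA_real_ else mean(x, na.rm = TRUE)
    }
    data.frame(
      muscle = strat$muscle[i], phase = strat$phase[i], n_pulses = n,
      proportion_excitatory = sum(s$label == "excitatory") / n,
      proportion_inhibitory = sum(s$label == "inhibitory") / n,
      proportion_failure = sum(s$label == "failure") / n,
      mean_delta_excitatory = mean_by(s$delta_density, "excitatory"),
      mean_delta_inhibitory = mean_by(s$delta_density, "inhibitory"),
      mean_amp_change_excitatory = mean_by(amp_change, "excitatory"),
      mean_amp_change_inhibitory = mean_by(amp_change, "inhibitory")
    )
  })
  structure(list(strata = do.call(rbind, rows),
                 n_excluded = sum(responses$excluded)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("<response_summary> %d strata, %d pulses excluded\n",
              nrow(x$strata), x$n_excluded))
  print(x$strata)
  invisible(x)
}

#' Correlate a response metric with the locomotor score
#'
#' Ordinary least squares of a per-session response metric (e.g.
#' failure proportion) against the 20-point locomotor score, with the
#' Pearson correlation and a rank-based (Spearman) correlation
#' alongside.
#'
#' @param score locomotor scores in \[0, 20\], one per session (>= 3).
#' @param metric response metric per session.
#' @return list: `slope`, `intercept`, `r`, `p`, `spearman_rho`,
#'   `spearman_p`, `n`; correlations are NA with a note when either
#'   variable has zero variance.
#' @export
score_response_correlation <- function(score, metric) {
  stopifnot(length(score) == length(metric), length(score) >= 3L,
            all(score >= 0 & score <= 20))
  n <- length(score)
  if (stats::sd(score) == 0 || stats::sd(metric) == 0) {
    fit <- if (stats::sd(score) > 0) stats::lm(metric ~ score) else NULL
    return(list(slope = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[2]),
                intercept = if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[1]),
                r = NA_real_, p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                n = n, note = "correlation undefined: zero variance"))
  }
  fit <- stats::lm(metric ~ score)
  ct <- stats::cor.test(score, metric, method = "pearson")
  cs <- suppressWarnings(stats::cor.test(score, metric, method = "spearman"))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value,
       spearman_rho = unname(cs$estimate), spearman_p = cs$p.value,
       n = n)
}
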