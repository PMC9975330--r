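#' EMG record
#'
#' Multichannel EMG traces in mV with a rest-interval annotation used
#' for background estimation. Channels follow the muscle naming of the
#' recording setup (LTA/LGL/RTA/RGL: left/right tibialis anterior,
#' ankle flexor, and gastrocnemius lateralis, ankle extensor); any
#' subset may be present.
#'
#' @param channels named list of numeric traces (mV), equal lengths.
#' @param sample_rate samples per second (nominally 10000).
#' @param rest_interval `c(start_s, end_s)` of a quiet interval, at
#'   least 0.5 s, within the record span.
#' @return an object of class `emg_record`.
#' @export
emg_record <- function(channels, sample_rate, rest_interval) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), sample_rate > 0)
  n <- unique(vapply(channels, length, integer(1)))
  stopifnot(length(n) == 1L)
  span <- n / sample_rate
  stopifnot(length(rest_interval) == 2L,
            rest_interval[1] >= 0, rest_interval[2] <= span + 1e-9,
            diff(rest_interval) >= 0.5)
  structure(list(channels = channels, sample_rate = sample_rate,
                 rest_interval = rest_interval, n_samples = n),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %s: %.1f s at %g kHz, rest [%.2f, %.2f] s\n",
              paste(names(x$channels), collapse = ", "),
              x$n_samples / x$sample_rate, x$sample_rate / 1000,
              x$rest_interval[1], x$rest_interval[2]))
  invisible(x)
}

#' Read an EMG record from delimited text
#'
#' Expects a column `time_s` plus one column per channel (mV). The rest
#' interval comes from a JSON sidecar (`<path>.json` with field
#' `rest_interval`) or the `rest_interval` argument.
#'
#' @param path delimited text file.
#' @param rest_interval optional `c(start_s, end_s)` override.
#' @return an [emg_record()].
#' @export
read_emg <- function(path, rest_interval = NULL) {
  tab <- utils::read.delim(path, sep = "", header = TRUE)
  if (ncol(tab) == 1L) tab <- utils::read.csv(path)
  stopifnot("time_s" %in% names(tab), nrow(tab) >= 2L)
  fs <- 1 / stats::median(diff(tab$time_s))
  if (is.null(rest_interval)) {
    side <- paste0(path, ".json")
    if (file.exists(side)) {
      rest_interval <- unlist(jsonlite::read_json(side)$rest_interval)
    } else stop("no rest interval given and no JSON sidecar found")
  }
  chans <- as.list(tab[setdiff(names(tab), "time_s")])
  emg_record(chans, sample_rate = fs, rest_interval = rest_interval)
}

# Zero-phase high-pass filter (Butterworth design applied forward and
# backward); removes movement artifact and baseline drift before
# rectification. cutoff_hz = NULL disables filtering.
highpass_rectify <- function(x, sample_rate, cutoff_hz = 100, order = 4L) {
  if (!is.null(cutoff_hz)) {
    bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  abs(x)
}

#' Motor-spike detection threshold
#'
#' Five times the mean of the rectified background signal over the
#' annotated rest interval, after high-pass filtering.
#'
#' @param record an [emg_record()].
#' @param channel channel name.
#' @param factor threshold multiple of the rest mean (5 by default).
#' @param highpass_hz high-pass cutoff in Hz (`NULL` to skip filtering).
#' @return threshold in mV.
#' @export
estimate_threshold <- function(record, channel, factor = 5,
                               highpass_hz = 100) {
  stopifnot(inherits(record, "emg_record"), channel %in% names(record$channels))
  rect <- highpass_rectify(record$channels[[channel]], record$sample_rate,
                           cutoff_hz = highpass_hz)
  i0 <- floor(record$rest_interval[1] * record$sample_rate) + 1L
  i1 <- min(record$n_samples,
            ceiling(record$rest_interval[2] * record$sample_rate))
  m <- mean(rect[i0:i1])
  if (m == 0) stop("zero background")
  factor * m
}

#' Extract motor spikes from an EMG channel
#'
#' A motor spike is the onset of a supra-threshold excursion of the
#' rectified (high-pass filtered) trace. Crossings within the dead time
#' of an accepted spike are merged into it; the spike amplitude is the
#' peak rectified value within the dead-time window after onset. The
#' 2-ms default dead time separates successive motor-unit potentials at
#' 10 kHz without merging whole bursts.
#'
#' @param record an [emg_record()].
#' @param channel channel name.
#' @param threshold_mV detection threshold (> 0), typically from
#'   [estimate_threshold()].
#' @param dead_time_s minimum spike separation in seconds.
#' @param highpass_hz high-pass cutoff in Hz (`NULL` to skip filtering).
#' @return object of class `spike_train` with `spike_times_s` (onset
#'   times, strictly increasing), `amplitudes_mV` and the threshold
#'   used. An empty train is allowed.
#' @export
extract_spikes <- function(record, channel, threshold_mV,
                           dead_time_s = 0.002, highpass_hz = 100) {
  stopifnot(inherits(record, "emg_record"), threshold_mV > 0)
  fs <- record$sample_rate
  rect <- highpass_rectify(record$channels[[channel]], fs,
                           cutoff_hz = highpass_hz)
  above <- rect >= threshold_mV
  onset <- which(above & !c(FALSE, above[-length(above)]))
  dead_n <- max(1L, as.integer(round(dead_time_s * fs)))
  times <- numeric(0); amps <- numeric(0)
  last <- -Inf
  for (i in onset) {
    tt <- (i - 1) / fs
    if (tt - last < dead_time_s) next
    j <- min(length(rect), i + dead_n - 1L)
    times <- c(times, tt)
    amps <- c(amps, max(rect[i:j]))
    last <- tt
  }
  spike_train(channel = channel, spike_times_s = times,
              amplitudes_mV = amps, threshold_mV = threshold_mV)
}

#' Spike train container
#'
#' @param channel channel name.
#' @param spike_times_s strictly increasing spike onset times, s.
#' @param amplitudes_mV peak rectified amplitude per spike.
#' @param threshold_mV detection threshold used.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(channel, spike_times_s, amplitudes_mV,
                        threshold_mV = NA_real_) {
  stopifnot(length(spike_times_s) == length(amplitudes_mV),
            !is.unsorted(spike_times_s, strictly = TRUE))
  structure(list(channel = channel, spike_times_s = spike_times_s,
                 amplitudes_mV = amplitudes_mV, threshold_mV = threshold_mV),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes (threshold %.3g mV)\n",
              x$channel, length(x$spike_times_s), x$threshold_mV))
  invisible(x)
}
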