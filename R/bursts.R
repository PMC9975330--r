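#' Detect EMG bursts from spike density
#'
#' The motor-spike density (spikes/s) is estimated by Gaussian-kernel
#' smoothing of the spike train on a regular grid. A burst opens when
#' the density rises above the on-threshold and closes when it falls
#' below the off-threshold (hysteresis suppresses flicker at the burst
#' edges); bursts shorter than `min_burst_ms` are discarded. The
#' default thresholds are relative to the trace-wide mean of the
#' nonzero density, so they adapt to the overall firing level. When the
#' raw record is supplied, the integrated amplitude of each burst is
#' the integral of the rectified filtered trace over the burst window.
#'
#' @param train a [spike_train()] with at least one spike.
#' @param record optional [emg_record()] for integrated amplitude.
#' @param channel channel of `record` to integrate (defaults to the
#'   train's channel).
#' @param kernel_sd_s Gaussian kernel SD in seconds (20 ms default).
#' @param grid_hz density evaluation rate (1 kHz default).
#' @param on_frac,off_frac on/off thresholds as fractions of the mean
#'   nonzero density.
#' @param min_burst_ms minimum burst duration.
#' @param end_s optional span end for the density grid; defaults to the
#'   record span or last spike + 4 kernel SD.
#' @param highpass_hz high-pass cutoff used for the integrated trace.
#' @return object of class `burst_set`: data frame `bursts` (`onset_s`,
#'   `offset_s`, `duration_s`, `integrated_amplitude`, `spike_count`)
#'   plus the density series and thresholds. Empty with a warning when
#'   the density never reaches the on-threshold.
#' @export
detect_bursts <- function(train, record = NULL, channel = NULL,
                          kernel_sd_s = 0.020, grid_hz = 1000,
                          on_frac = 0.5, off_frac = 0.25,
                          min_burst_ms = 30, end_s = NULL,
                          highpass_hz = 100) {
  stopifnot(inherits(train, "spike_train"))
  st <- train$spike_times_s
  if (length(st) < 1L) stop("no spikes")
  if (is.null(end_s)) {
    end_s <- if (!is.null(record)) record$n_samples / record$sample_rate
             else max(st) + 4 * kernel_sd_s
  }
  dt <- 1 / grid_hz
  grid <- seq(0, end_s, by = dt)
  counts <- tabulate(pmin(length(grid), floor(st / dt) + 1L),
                     nbins = length(grid))
  half <- ceiling(4 * kernel_sd_s / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = kernel_sd_s)
  dens <- stats::convolve(counts, rev(kern), type = "open")
  dens <- dens[(half + 1):(half + length(grid))]   # spikes/s
  on_thr <- on_frac * mean(dens[dens > max(dens) * 1e-9])
  off_thr <- off_frac / on_frac * on_thr
  inb <- FALSE; onsets <- numeric(0); offsets <- numeric(0)
  for (i in seq_along(dens)) {
    if (!inb && dens[i] >= on_thr) { inb <- TRUE; onsets <- c(onsets, grid[i]) }
    else if (inb && dens[i] < off_thr) { inb <- FALSE; offsets <- c(offsets, grid[i]) }
  }
  if (inb) offsets <- c(offsets, grid[length(grid)])
  keep <- (offsets - onsets) >= min_burst_ms / 1000
  onsets <- onsets[keep]; offsets <- offsets[keep]
  if (length(onsets) == 0L) {
    warning("no bursts: spike density never reaches the on-threshold")
  }
  integ <- rep(NA_real_, length(onsets))
  if (!is.null(record) && length(onsets)) {
    channel <- channel %||% train$channel
    fs <- record$sample_rate
    rect <- highpass_rectify(record$channels[[channel]], fs,
                             cutoff_hz = highpass_hz)
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] * fs) + 1L
      i1 <- min(record$n_samples, ceiling(offsets[k] * fs))
      integ[k] <- sum(rect[i0:i1]) / fs
    }
  }
  counts_in <- vapply(seq_along(onsets), function(k) {
    sum(st >= onsets[k] & st < offsets[k])
  }, integer(1))
  structure(
    list(bursts = data.frame(onset_s = onsets, offset_s = offsets,
                             duration_s = offsets - onsets,
                             integrated_amplitude = integ,
                             spike_count = counts_in),
         density = data.frame(time_s = grid, rate_hz = dens),
         on_threshold = on_thr, off_threshold = off_thr),
    class = "burst_set"
  )
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts (on %.1f /s, off %.1f /s)\n",
              nrow(x$bursts), x$on_threshold, x$off_threshold))
  invisible(x)
}

#' Manually tagged bursts
#'
#' Builds a `burst_set` from onset/offset pairs, mirroring manual burst
#' selection; overrides density-based detection downstream.
#'
#' @param onset_s,offset_s burst windows, disjoint and ordered.
#' @return a `burst_set` (integrated amplitude and counts unset).
#' @export
manual_bursts <- function(onset_s, offset_s) {
  stopifnot(length(onset_s) == length(offset_s), all(offset_s > onset_s),
            !is.unsorted(onset_s, strictly = TRUE))
  structure(
    list(bursts = data.frame(onset_s = onset_s, offset_s = offset_s,
                             duration_s = offset_s - onset_s,
                             integrated_amplitude = NA_real_,
                             spike_count = NA_integer_),
         density = NULL, on_threshold = NA_real_, off_threshold = NA_real_),
    class = "burst_set"
  )
}

#' Segment step cycles from flexor bursts and partition into epochs
#'
#' The reference muscle is the tibialis anterior (flexor): cycle k runs
#' from flexor burst onset k to onset k + 1 (half-open). Each cycle is
#' divided into 5 equal epochs; epochs 1-2 are the flexor-active
#' (swing) phase, epochs 3-5 the extensor-active (stance) phase.
#'
#' @param flexor_bursts a `burst_set` with at least two bursts.
#' @return object of class `epoch_partition`: data frame `cycles`
#'   (`start_s`, `end_s`) and matrix `epoch_breaks` (n_cycles x 6
#'   boundary times).
#' @export
segment_cycles <- function(flexor_bursts) {
  stopifnot(inherits(flexor_bursts, "burst_set"))
  on <- flexor_bursts$bursts$onset_s
  if (length(on) < 2L) stop("cannot form cycles")
  start <- on[-length(on)]; end <- on[-1]
  breaks <- t(vapply(seq_along(start), function(k) {
    start[k] + (end[k] - start[k]) * (0:5) / 5
  }, numeric(6)))
  structure(list(cycles = data.frame(start_s = start, end_s = end),
                 epoch_breaks = breaks,
                 epoch_roles = c("swing", "swing", "stance", "stance", "stance")),
            class = "epoch_partition")
}

#' @export
print.epoch_partition <- function(x, ...) {
  cat(sprintf("<epoch_partition> %d cycles x 5 epochs\n", nrow(x$cycles)))
  invisible(x)
}

#' Flexor/extensor burst alternation
#'
#' For each flexor burst, the fraction of its duration that overlaps
#' any extensor burst: 0 under strict alternation, 1 under full
#' co-activation. Also returns paired flexor/extensor activity
#' durations per flexor-anchored cycle for plotting.
#'
#' @param flexor,extensor `burst_set` objects, both nonempty.
#' @return data frame with one row per flexor burst: `flexor_onset_s`,
#'   `flexor_duration_s`, `extensor_duration_s` (extensor burst time
#'   inside the flexor-anchored cycle), `overlap_fraction`.
#' @export
burst_alternation <- function(flexor, extensor) {
  stopifnot(inherits(flexor, "burst_set"), inherits(extensor, "burst_set"),
            nrow(flexor$bursts) > 0L, nrow(extensor$bursts) > 0L)
  fb <- flexor$bursts; eb <- extensor$bursts
  overlap_len <- function(a0, a1) {
    sum(pmax(0, pmin(a1, eb$offset_s) - pmax(a0, eb$onset_s)))
  }
  n <- nrow(fb)
  cycle_end <- c(fb$onset_s[-1], Inf)
  data.frame(
    flexor_onset_s = fb$onset_s,
    flexor_duration_s = fb$duration_s,
    extensor_duration_s = vapply(seq_len(n), function(k) {
      overlap_len(fb$onset_s[k], cycle_end[k])
    }, numeric(1)),
    overlap_fraction = vapply(seq_len(n), function(k) {
      overlap_len(fb$onset_s[k], fb$offset_s[k]) / fb$duration_s[k]
    }, numeric(1))
  )
}
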