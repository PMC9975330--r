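#' Open-field neck-marker trajectory
#'
#' Arena-coordinate positions of the neck marker (cm) around a
#' photostimulation train, nominally filmed at 100 frames/s.
#'
#' @param x_cm,y_cm per-frame positions.
#' @param frame_rate frames per second.
#' @param stim_onset_s,stim_offset_s stimulation interval within the
#'   record span (trains last 1 s).
#' @param time_s optional per-frame times; defaults to a regular grid.
#' @return an object of class `trajectory2d`.
#' @export
trajectory2d <- function(x_cm, y_cm, frame_rate, stim_onset_s,
                         stim_offset_s, time_s = NULL) {
  stopifnot(length(x_cm) == length(y_cm), frame_rate > 0)
  n <- length(x_cm)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / frame_rate
  stopifnot(stim_onset_s >= time_s[1], stim_onset_s < stim_offset_s,
            stim_onset_s <= time_s[n])
  structure(list(time_s = time_s, x_cm = x_cm, y_cm = y_cm,
                 frame_rate = frame_rate, stim_onset_s = stim_onset_s,
                 stim_offset_s = stim_offset_s),
            class = "trajectory2d")
}

#' Read an open-field trajectory from delimited text
#'
#' Columns `time_s`, `x_cm`, `y_cm`; stimulation timing from a JSON
#' sidecar (`<path>.json`, fields `stim_onset_s`, `stim_offset_s`) or
#' the arguments.
#'
#' @param path delimited text file.
#' @param stim_onset_s,stim_offset_s optional overrides.
#' @return a [trajectory2d()].
#' @export
read_trajectory <- function(path, stim_onset_s = NULL, stim_offset_s = NULL) {
  tab <- utils::read.delim(path, sep = "", header = TRUE)
  if (ncol(tab) == 1L) tab <- utils::read.csv(path)
  if (is.null(stim_onset_s)) {
    side <- paste0(path, ".json")
    stopifnot(file.exists(side))
    j <- jsonlite::read_json(side)
    stim_onset_s <- j$stim_onset_s; stim_offset_s <- j$stim_offset_s
  }
  fr <- 1 / stats::median(diff(tab$time_s))
  trajectory2d(tab$x_cm, tab$y_cm, frame_rate = fr,
               stim_onset_s = stim_onset_s, stim_offset_s = stim_offset_s,
               time_s = tab$time_s)
}

smooth_traj <- function(traj, window = 5L) {
  list(x = moving_average(traj$x_cm, window),
       y = moving_average(traj$y_cm, window))
}

#' Binned locomotor speed profile
#'
#' Path length per time bin divided by the bin duration, after
#' moving-average smoothing of the trajectory; 100-ms bins reproduce
#' the per-trial speed matrices of the overground analyses.
#'
#' @param traj a [trajectory2d()].
#' @param bin_s bin width in seconds.
#' @param smooth_window smoothing window in frames.
#' @return data frame `bin_start_s`, `bin_end_s`, `speed_cm_s`.
#' @export
speed_profile <- function(traj, bin_s = 0.100, smooth_window = 5L) {
  sm <- smooth_traj(traj, smooth_window)
  t <- traj$time_s
  n <- length(t)
  step_len <- sqrt(diff(sm$x)^2 + diff(sm$y)^2)   # step i: t[i] -> t[i+1]
  bin <- floor((t[-n] - t[1]) / bin_s + 1e-9)
  tot <- tapply(step_len, bin, sum)
  ids <- as.integer(names(tot))
  start <- t[1] + ids * bin_s
  end <- pmin(start + bin_s, t[n])
  data.frame(bin_start_s = start, bin_end_s = end,
             speed_cm_s = as.numeric(tot) / (end - start))
}

#' Detect initiation of a locomotor bout
#'
#' Displacement is measured as straight-line distance from the position
#' at stimulation onset. A locomotor bout is a displacement exceeding
#' `radius_cm` (the 10-cm circle criterion for full-body movement)
#' within `horizon_s` of stimulation onset; the latency is the first
#' crossing time. `initiated_within_stim` flags bouts whose latency
#' falls within the stimulation train (1 s).
#'
#' @param traj a [trajectory2d()].
#' @param radius_cm bout circle radius.
#' @param horizon_s post-onset horizon over which displacements count.
#' @return object of class `bout_result`: `is_bout`, `latency_s` (NA if
#'   no crossing), `displacement_cm` (maximal net displacement within
#'   the horizon), `initiated_within_stim`, `truncated` (TRUE when the
#'   record ends before the full horizon).
#' @export
detect_initiation <- function(traj, radius_cm = 10, horizon_s = 3) {
  stopifnot(inherits(traj, "trajectory2d"))
  t <- traj$time_s
  i0 <- which(t >= traj$stim_onset_s)[1]
  if (is.na(i0) || is.na(traj$x_cm[i0]) || is.na(traj$y_cm[i0])) {
    stop("untracked onset")
  }
  truncated <- t[length(t)] < traj$stim_onset_s + horizon_s
  sel <- which(t >= traj$stim_onset_s & t <= traj$stim_onset_s + horizon_s)
  disp <- sqrt((traj$x_cm[sel] - traj$x_cm[i0])^2 +
               (traj$y_cm[sel] - traj$y_cm[i0])^2)
  cross <- which(disp > radius_cm)
  latency <- if (length(cross)) t[sel[cross[1]]] - traj$stim_onset_s else NA_real_
  stim_dur <- traj$stim_offset_s - traj$stim_onset_s
  structure(list(
    is_bout = length(cross) > 0L,
    latency_s = latency,
    displacement_cm = max(disp, na.rm = TRUE),
    initiated_within_stim = isTRUE(latency <= stim_dur),
    truncated = truncated
  ), class = "bout_result")
}

#' @export
print.bout_result <- function(x, ...) {
  cat(sprintf("<bout_result> bout: %s, latency %.2f s, displacement %.1f cm\n",
              x$is_bout, x$latency_s, x$displacement_cm))
  invisible(x)
}

#' Heading vector and trial classification
#'
#' The heading vector is the net displacement over the first
#' `heading_window_s` of stimulation. Trials are classified as
#' `straight_locomotion` (a bout occurs and the heading-window
#' displacement reaches `rotation_radius_cm`), `rotation` (movement
#' above the tracking-noise floor that stays confined within
#' `rotation_radius_cm`, the displacement-based reading of the
#' body-rotation-without-displacement trials), or `no_response`.
#' Movement is judged on the smoothed trajectory over the bout horizon:
#' the maximal displacement must exceed both the tracking-noise floor
#' (3x the jitter SD, estimated as the residual of the raw positions
#' around the smoothed trajectory over the 1 s preceding stimulation)
#' and an absolute minimum body movement of `movement_min_cm`, below
#' which a neck-marker excursion does not count as movement.
#'
#' @param traj a [trajectory2d()].
#' @param heading_window_s heading window (0.5 s default).
#' @param rotation_radius_cm confinement radius (5 cm default).
#' @param radius_cm,horizon_s bout criterion, as [detect_initiation()].
#' @param movement_min_cm minimum displacement counting as movement.
#' @param smooth_window smoothing window in frames.
#' @return list with `heading_vector` (`c(dx, dy)` in cm),
#'   `trial_class`, `noise_floor_cm` and `max_displacement_cm`.
#' @export
heading_classification <- function(traj, heading_window_s = 0.500,
                                   rotation_radius_cm = 5,
                                   radius_cm = 10, horizon_s = 3,
                                   movement_min_cm = 1,
                                   smooth_window = 5L) {
  stopifnot(inherits(traj, "trajectory2d"))
  t <- traj$time_s
  i0 <- which(t >= traj$stim_onset_s)[1]
  i1 <- which(t >= traj$stim_onset_s + heading_window_s)[1]
  if (is.na(i0) || is.na(i1)) stop("tracked frames do not cover the heading window")
  heading <- c(dx = traj$x_cm[i1] - traj$x_cm[i0],
               dy = traj$y_cm[i1] - traj$y_cm[i0])
  sm <- smooth_traj(traj, smooth_window)
  pre <- which(t >= traj$stim_onset_s - 1 & t < traj$stim_onset_s)
  noise_floor <- if (length(pre) >= 5L) {
    3 * stats::sd(sqrt((traj$x_cm[pre] - sm$x[pre])^2 +
                       (traj$y_cm[pre] - sm$y[pre])^2))
  } else 0.25
  noise_floor <- max(noise_floor, movement_min_cm)
  sel <- which(t >= traj$stim_onset_s & t <= traj$stim_onset_s + horizon_s)
  disp_sm <- sqrt((sm$x[sel] - sm$x[i0])^2 + (sm$y[sel] - sm$y[i0])^2)
  max_disp <- max(disp_sm, na.rm = TRUE)
  bout <- detect_initiation(traj, radius_cm = radius_cm,
                            horizon_s = horizon_s)$is_bout
  trial_class <- if (bout && sqrt(sum(heading^2)) >= rotation_radius_cm) {
    "straight_locomotion"
  } else if (max_disp > noise_floor && max_disp <= rotation_radius_cm) {
    "rotation"
  } else if (max_disp <= noise_floor) {
    "no_response"
  } else if (bout) "straight_locomotion" else "no_response"
  list(heading_vector = heading, trial_class = trial_class,
       noise_floor_cm = noise_floor, max_displacement_cm = max_disp)
}

#' Session-level initiation statistics
#'
#' @param bouts list of `bout_result` objects (one per trial).
#' @return list: `n_trials`, `fraction_bouts`,
#'   `fraction_initiated_within_stim` (denominator: all trials) and the
#'   pooled defined latencies.
#' @export
session_initiation_stats <- function(bouts) {
  stopifnot(length(bouts) >= 1L)
  is_bout <- vapply(bouts, `[[`, logical(1), "is_bout")
  within <- vapply(bouts, `[[`, logical(1), "initiated_within_stim")
  lat <- vapply(bouts, `[[`, numeric(1), "latency_s")
  list(n_trials = length(bouts),
       fraction_bouts = mean(is_bout),
       fraction_initiated_within_stim = mean(within),
       latencies_s = lat[!is.na(lat)])
}
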