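#' Per-cycle gait metrics
#'
#' For each complete stance-to-stance cycle: stride length (absolute
#' toe advance between consecutive stance onsets), step height (peak
#' toe height during swing minus mean toe height during the preceding
#' stance), and the angular excursion (max - min) of each joint angle.
#' Also returns the iliac-crest height time series (a posture proxy),
#' optionally normalized to its mean over a pre-stimulation baseline
#' window, and the overall step frequency (cycles per second).
#'
#' @param markers a [marker_series()].
#' @param events a [gait_events()]; the swing onset inside each cycle
#'   splits stance from swing.
#' @param segs optional [segment_lengths()] used to compute joint
#'   angles when `angles` is not supplied.
#' @param angles optional precomputed `joint_angles`.
#' @param baseline_window optional `c(start_s, end_s)`; when given the
#'   iliac-crest height series is divided by its mean over this window.
#' @return object of class `gait_metrics`: a per-cycle data frame
#'   (`cycle_start_s`, `stride_length_cm`, `step_height_cm`,
#'   `hip_excursion_deg`, `knee_excursion_deg`, `ankle_excursion_deg`),
#'   the `iliac_crest_height` series, and `step_frequency_hz`.
#' @export
gait_metrics <- function(markers, events, segs = NULL, angles = NULL,
                         baseline_window = NULL) {
  stopifnot(inherits(markers, "marker_series"), inherits(events, "gait_events"))
  cyc <- gait_cycles(events)
  if (nrow(cyc) == 0L) stop("no cycles")
  if (is.null(angles)) angles <- compute_joint_angles(markers, segs = segs)
  t <- markers$time_s
  toe_x <- markers$coords$toe_x
  toe_y <- markers$coords$toe_y
  at_time <- function(v, when) v[which.min(abs(t - when))]
  rows <- lapply(seq_len(nrow(cyc)), function(k) {
    idx <- cycle_frames(t, cyc$start[k], cyc$end[k])
    sw <- events$swing_onsets[events$swing_onsets > cyc$start[k] &
                              events$swing_onsets < cyc$end[k]]
    stride <- abs(at_time(toe_x, cyc$end[k]) - at_time(toe_x, cyc$start[k]))
    step_h <- NA_real_
    if (length(sw) >= 1L) {
      stance_idx <- idx[t[idx] < sw[1]]
      swing_idx <- idx[t[idx] >= sw[1]]
      if (length(stance_idx) && length(swing_idx) &&
          !anyNA(toe_y[c(stance_idx, swing_idx)])) {
        step_h <- max(toe_y[swing_idx]) - mean(toe_y[stance_idx])
      }
    }
    exc <- vapply(c("hip", "knee", "ankle"), function(j) {
      y <- angles[[paste0(j, "_deg")]][idx]
      if (anyNA(y)) NA_real_ else max(y) - min(y)
    }, numeric(1))
    missing_toe <- anyNA(toe_x[idx]) || anyNA(toe_y[idx])
    data.frame(cycle_start_s = cyc$start[k], cycle_end_s = cyc$end[k],
               stride_length_cm = if (missing_toe) NA_real_ else stride,
               step_height_cm = step_h,
               hip_excursion_deg = exc[["hip"]],
               knee_excursion_deg = exc[["knee"]],
               ankle_excursion_deg = exc[["ankle"]],
               missing = missing_toe)
  })
  per_cycle <- do.call(rbind, rows)
  crest <- markers$coords$iliac_crest_y
  crest_norm <- NULL
  if (!is.null(baseline_window)) {
    sel <- t >= baseline_window[1] & t < baseline_window[2]
    base <- mean(crest[sel], na.rm = TRUE)
    if (!is.finite(base) || base == 0) stop("empty or degenerate baseline window")
    crest_norm <- crest / base
  }
  total_span <- cyc$end[nrow(cyc)] - cyc$start[1]
  structure(
    list(per_cycle = per_cycle,
         iliac_crest_height = data.frame(time_s = t, height_cm = crest,
                                         normalized = crest_norm %||% NA_real_),
         step_frequency_hz = nrow(cyc) / total_span),
    class = "gait_metrics"
  )
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf("<gait_metrics> %d cycles, step frequency %.2f Hz\n",
              nrow(x$per_cycle), x$step_frequency_hz))
  invisible(x)
}
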