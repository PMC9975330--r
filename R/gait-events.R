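#' Gait events
#'
#' Times (s) of stance onsets (foot contact) and swing onsets
#' (lift-off). Onsets of the two kinds alternate; intervals are
#' half-open `[start, end)`.
#'
#' @param stance_onsets,swing_onsets increasing times in seconds.
#' @param source `"manual"` or `"automatic"`.
#' @return an object of class `gait_events`.
#' @export
gait_events <- function(stance_onsets, swing_onsets,
                        source = c("automatic", "manual")) {
  source <- match.arg(source)
  stance_onsets <- as.numeric(stance_onsets)
  swing_onsets <- as.numeric(swing_onsets)
  stopifnot(!is.unsorted(stance_onsets, strictly = TRUE),
            !is.unsorted(swing_onsets, strictly = TRUE))
  if (length(stance_onsets) && length(swing_onsets)) {
    ev <- rbind(data.frame(time = stance_onsets,
                           type = rep("stance_onset", length(stance_onsets))),
                data.frame(time = swing_onsets,
                           type = rep("swing_onset", length(swing_onsets))))
    ev <- ev[order(ev$time), ]
    if (nrow(ev) > 1L && any(ev$type[-1] == ev$type[-nrow(ev)])) {
      stop("stance and swing onsets must alternate")
    }
  }
  structure(list(stance_onsets = stance_onsets, swing_onsets = swing_onsets,
                 source = source),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d stance onsets, %d swing onsets (%s)\n",
              length(x$stance_onsets), length(x$swing_onsets), x$source))
  invisible(x)
}

#' Detect gait events from the toe trajectory
#'
#' Ground contact is detected as runs of frames in which the toe height
#' stays below a threshold for at least `min_contact_ms`. A stance
#' onset is the first frame of a contact run; a swing onset is the
#' first frame after it. The default threshold, the 10th percentile of
#' toe height plus 0.1 cm, adapts to the ground level of the recording.
#' Manual event files ([read_gait_events()]) take precedence over
#' automatic detection when available.
#'
#' @param markers a [marker_series()].
#' @param height_threshold_cm contact threshold for toe height; `NULL`
#'   (default) uses `quantile(toe_y, 0.1) + 0.1`.
#' @param min_contact_ms minimum duration of a contact run, ms.
#' @return a [gait_events()] with `source = "automatic"`; empty (with a
#'   warning) when the toe never crosses the threshold band.
#' @export
detect_gait_events <- function(markers, height_threshold_cm = NULL,
                               min_contact_ms = 20) {
  stopifnot(inherits(markers, "marker_series"))
  toe_y <- markers$coords$toe_y
  t <- markers$time_s
  if (is.null(height_threshold_cm)) {
    height_threshold_cm <-
      stats::quantile(toe_y, 0.1, na.rm = TRUE, names = FALSE) + 0.1
  }
  contact <- !is.na(toe_y) & toe_y < height_threshold_cm
  min_run <- max(1L, as.integer(round(min_contact_ms / 1000 * markers$frame_rate)))
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep) || all(contact) || !any(contact)) {
    warning("no gait events detected: toe height never crosses the threshold band")
    return(gait_events(numeric(0), numeric(0), source = "automatic"))
  }
  st_idx <- starts[keep]
  sw_idx <- ends[keep] + 1L
  sw_idx <- sw_idx[sw_idx <= length(toe_y)]
  # drop a stance onset at the very first frame: contact state unknown before
  st_idx <- st_idx[st_idx > 1L]
  gait_events(stance_onsets = t[st_idx], swing_onsets = t[sw_idx],
              source = "automatic")
}

# Complete stance-to-stance cycles as a data.frame(start, end, duration).
gait_cycles <- function(events) {
  so <- events$stance_onsets
  if (length(so) < 2L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0)))
  }
  data.frame(start = so[-length(so)], end = so[-1],
             duration = diff(so))
}
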