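#' Marker frame series
#'
#' Container for time-indexed sagittal-plane marker coordinates of the
#' hindlimb (iliac crest, hip, ankle, toe, and optionally knee), in cm,
#' with x rostral-positive and y dorsal-positive. Missing markers are
#' encoded as `NA` coordinates.
#'
#' @param frame_rate frames per second (> 0); treadmill kinematics are
#'   nominally recorded at 250 frames/s.
#' @param coords data frame with columns `<marker>_x`, `<marker>_y` for
#'   markers `iliac_crest`, `hip`, `ankle`, `toe` and optionally `knee`,
#'   one row per frame in time order.
#' @param time_s optional per-frame times in seconds; defaults to
#'   `(0:(n-1)) / frame_rate`.
#' @return an object of class `marker_series`.
#' @export
marker_series <- function(coords, frame_rate, time_s = NULL) {
  stopifnot(is.data.frame(coords), frame_rate > 0)
  req <- c("hip", "ankle", "toe", "iliac_crest")
  for (m in req) {
    if (!all(paste0(m, c("_x", "_y")) %in% names(coords))) {
      stop("marker '", m, "' missing from coordinate table")
    }
  }
  n <- nrow(coords)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / frame_rate
  stopifnot(length(time_s) == n, !is.unsorted(time_s, strictly = TRUE))
  structure(
    list(frame_rate = frame_rate, time_s = time_s, coords = coords,
         has_knee = all(c("knee_x", "knee_y") %in% names(coords))),
    class = "marker_series"
  )
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %d frames at %g frames/s (%.2f s)%s\n",
              nrow(x$coords), x$frame_rate,
              diff(range(x$time_s)),
              if (x$has_knee) ", knee tracked" else ", knee inferred"))
  invisible(x)
}

#' Hindlimb segment lengths
#'
#' Femur and tibia lengths (cm) used to infer the knee position by
#' triangulation, avoiding skin-slippage error of a tracked knee marker.
#'
#' @param femur_cm,tibia_cm strictly positive segment lengths in cm.
#' @return an object of class `segment_lengths`.
#' @export
segment_lengths <- function(femur_cm, tibia_cm) {
  stopifnot(is.numeric(femur_cm), is.numeric(tibia_cm),
            femur_cm > 0, tibia_cm > 0)
  structure(list(femur_cm = femur_cm, tibia_cm = tibia_cm),
            class = "segment_lengths")
}

#' Read marker coordinates from delimited text
#'
#' Accepts either wide form (`time_s`, `<marker>_x`, `<marker>_y`, ...) or
#' long form (`time_s`, `marker`, `x_cm`, `y_cm`).
#'
#' @param path file path of a tab- or comma-delimited text table.
#' @param frame_rate frames per second of the recording.
#' @return a [marker_series()].
#' @export
read_markers <- function(path, frame_rate) {
  tab <- utils::read.delim(path, sep = "", header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("marker", "x_cm", "y_cm") %in% names(tab))) {
    # long -> wide
    times <- sort(unique(tab$time_s))
    wide <- data.frame(row.names = seq_along(times))
    for (m in unique(tab$marker)) {
      sub <- tab[tab$marker == m, ]
      ix <- match(times, sub$time_s)
      wide[[paste0(m, "_x")]] <- sub$x_cm[ix]
      wide[[paste0(m, "_y")]] <- sub$y_cm[ix]
    }
    return(marker_series(wide, frame_rate, time_s = times))
  }
  time_s <- tab$time_s
  tab$time_s <- NULL
  marker_series(tab, frame_rate, time_s = time_s)
}

#' Read manually tagged gait events from delimited text
#'
#' Expected columns: `time_s`, `event` (one of `stance_onset`,
#' `swing_onset`) and optionally `limb`. Manual files mirror manual
#' tagging of foot contact and lift-off and override automatic detection.
#'
#' @param path delimited text file.
#' @param limb optional limb label filter.
#' @return a [gait_events()] object with `source = "manual"`.
#' @export
read_gait_events <- function(path, limb = NULL) {
  tab <- utils::read.delim(path, sep = "", header = TRUE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) == 1L) tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_s", "event") %in% names(tab)))
  if (!is.null(limb) && "limb" %in% names(tab)) tab <- tab[tab$limb == limb, ]
  gait_events(stance_onsets = sort(tab$time_s[tab$event == "stance_onset"]),
              swing_onsets = sort(tab$time_s[tab$event == "swing_onset"]),
              source = "manual")
}

marker_xy <- function(markers, name) {
  cbind(x = markers$coords[[paste0(name, "_x")]],
        y = markers$coords[[paste0(name, "_y")]])
}
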