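# Alternating-extrema (turning point) detection with a prominence
# threshold: a maximum is confirmed once the trace has dropped by at
# least `prominence` below the running maximum, and symmetrically for
# minima, which enforces alternation and suppresses noise wiggles.
alternating_extrema <- function(y, prominence = 2) {
  n <- length(y)
  idx <- integer(0); typ <- character(0)
  imax <- 1L; imin <- 1L; dir <- 0L   # dir: +1 last was min, -1 last was max
  for (i in seq_len(n)) {
    if (y[i] > y[imax]) imax <- i
    if (y[i] < y[imin]) imin <- i
    if (dir >= 0L && y[i] <= y[imax] - prominence) {
      idx <- c(idx, imax); typ <- c(typ, "max")
      dir <- -1L; imin <- i
    } else if (dir <= 0L && y[i] >= y[imin] + prominence) {
      idx <- c(idx, imin); typ <- c(typ, "min")
      dir <- 1L; imax <- i
    }
  }
  data.frame(index = idx, type = typ, stringsAsFactors = FALSE)
}

#' Segment swim strokes from the hip angle
#'
#' The swim cycle is split at the extrema of the (smoothed) hip angle:
#' the power stroke runs from a hip-angle minimum to the next maximum,
#' the return stroke from a maximum to the next minimum. Each detected
#' maximum closes one power stroke (starting at the preceding minimum,
#' or at the start of the trace for the leading partial rise) and each
#' detected minimum closes one return stroke; a trailing segment that
#' never reaches its defining extremum is discarded. Strokes therefore
#' alternate and tile the span they cover. The swim frequency is
#' estimated from the spacing of same-type extrema,
#' `(n - 1) / (t_last - t_first)` over the maxima (falling back to the
#' minima), which is exact for periodic input.
#'
#' @param hip_deg per-frame hip angle in degrees.
#' @param frame_rate frames per second.
#' @param smooth_window moving-average window (frames) applied before
#'   extrema detection.
#' @param prominence_deg minimum rise/fall (degrees) for an extremum.
#' @return object of class `stroke_segmentation` with data frames
#'   `power_strokes` and `return_strokes` (`start_s`, `end_s`,
#'   `amplitude_deg`) and `swim_frequency_hz`.
#' @export
segment_swim_strokes <- function(hip_deg, frame_rate, smooth_window = 5L,
                                 prominence_deg = 2) {
  stopifnot(frame_rate > 0)
  t <- (seq_along(hip_deg) - 1) / frame_rate
  ys <- moving_average(hip_deg, smooth_window)
  ext <- alternating_extrema(ys, prominence = prominence_deg)
  if (nrow(ext) < 2L) stop("no strokes")
  et <- t[ext$index]; ev <- ys[ext$index]
  power <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      amplitude_deg = numeric(0))
  ret <- power
  prev_t <- t[1]; prev_v <- ys[1]
  for (k in seq_len(nrow(ext))) {
    if (et[k] > prev_t) {   # skip degenerate leading segments
      seg <- data.frame(start_s = prev_t, end_s = et[k],
                        amplitude_deg = abs(ev[k] - prev_v))
      if (ext$type[k] == "max") power <- rbind(power, seg)
      else ret <- rbind(ret, seg)
    }
    prev_t <- et[k]; prev_v <- ev[k]
  }
  maxima <- et[ext$type == "max"]
  minima <- et[ext$type == "min"]
  freq <- NA_real_
  if (length(maxima) >= 2L) {
    freq <- (length(maxima) - 1) / (maxima[length(maxima)] - maxima[1])
  } else if (length(minima) >= 2L) {
    freq <- (length(minima) - 1) / (minima[length(minima)] - minima[1])
  }
  structure(list(power_strokes = power, return_strokes = ret,
                 swim_frequency_hz = freq,
                 extrema = data.frame(time_s = et, value = ev,
                                      type = ext$type)),
            class = "stroke_segmentation")
}

#' @export
print.stroke_segmentation <- function(x, ...) {
  cat(sprintf(
    "<stroke_segmentation> %d power + %d return strokes, %.2f Hz\n",
    nrow(x$power_strokes), nrow(x$return_strokes), x$swim_frequency_hz))
  invisible(x)
}
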