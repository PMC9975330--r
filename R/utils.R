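# Internal numeric helpers shared across modules.

# Centered moving average; edges use the shrunken window that fits.
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Linear interpolation across interior NA runs of length <= max_gap.
# Leading/trailing NAs and longer runs are left as NA.
fill_gaps <- function(x, max_gap = 4L) {
  if (!anyNA(x)) return(x)
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) < 2L) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- x
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n) next          # edge gap: not interpolable
    if (r$lengths[k] > max_gap) next
    x0 <- x[s - 1L]; x1 <- x[e + 1L]
    w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1L)
    out[s:e] <- x0 + w * (x1 - x0)
  }
  out
}

# Circular summary of phase fractions in [0, 1).
circular_phase_stats <- function(phases) {
  stopifnot(is.numeric(phases))
  if (length(phases) == 0L) {
    return(list(mean_phase = NA_real_, R = NA_real_, n = 0L))
  }
  z <- mean(exp(2i * pi * phases))
  mp <- (Arg(z) / (2 * pi)) %% 1
  list(mean_phase = mp, R = Mod(z), n = length(phases))
}

# Smallest signed circular difference a - b on the unit cycle, in (-0.5, 0.5].
circ_diff <- function(a, b) {
  d <- (a - b) %% 1
  ifelse(d > 0.5, d - 1, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Frames of a half-open cycle [start, end); the small tolerance keeps
# boundary frames stable against floating-point drift in event times.
cycle_frames <- function(t, start, end, eps = 1e-9) {
  which(t >= start - eps & t < end - eps)
}
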