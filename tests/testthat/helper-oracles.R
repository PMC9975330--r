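# Brute-force sample-by-sample spike scan: the independent oracle for
# extract_spikes (same definition, naive loop implementation).
naive_spike_scan <- function(x, fs, threshold, dead_time_s = 0.002) {
  rect <- abs(x)
  dead_n <- max(1L, as.integer(round(dead_time_s * fs)))
  times <- numeric(0); amps <- numeric(0)
  last <- -Inf; prev_above <- FALSE
  for (i in seq_along(rect)) {
    above <- rect[i] >= threshold
    if (above && !prev_above) {
      tt <- (i - 1) / fs
      if (tt - last >= dead_time_s) {
        j <- min(length(rect), i + dead_n - 1L)
        times <- c(times, tt)
        amps <- c(amps, max(rect[i:j]))
        last <- tt
      }
    }
    prev_above <- above
  }
  list(times = times, amps = amps)
}

# Build an emg_record holding one channel from a raw trace.
trace_record <- function(x, fs = 10000, rest = c(0, 0.5), name = "LTA") {
  ch <- list(x)
  names(ch) <- name
  emg_record(ch, sample_rate = fs, rest_interval = rest)
}

# Joint-angle object built directly from per-frame vectors.
make_angles <- function(hip, knee = hip, ankle = hip, frame_rate = 250,
                        time_s = NULL) {
  n <- length(hip)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / frame_rate
  structure(list(frame_rate = frame_rate, time_s = time_s,
                 hip_deg = hip, knee_deg = rep_len(knee, n),
                 ankle_deg = rep_len(ankle, n),
                 missing = rep(FALSE, n), degraded = rep(FALSE, n)),
            class = "joint_angles")
}

# Random limb poses for triangulation round trips; angle ranges keep the
# knee on the rostral side of the hip-ankle chord (anatomical branch).
random_poses <- function(n, seed) {
  set.seed(seed)
  list(hip = runif(n, 60, 150), knee = runif(n, 50, 150),
       ankle = runif(n, 40, 150),
       segs = segment_lengths(runif(1, 1.2, 2), runif(1, 1.4, 2.4)))
}

# Which circle-intersection branch holds for a marker triple.
knee_branch <- function(hip, ankle, knee) {
  cr <- (ankle[1] - hip[1]) * (knee[2] - hip[2]) -
    (ankle[2] - hip[2]) * (knee[1] - hip[1])
  if (cr >= 0) "rostral" else "caudal"
}
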