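test_that("the motor-spike threshold is five times the rest mean", {
  # alternating +/- 0.02 mV: rectified mean exactly 0.02
  x <- rep(c(0.02, -0.02), 5000)
  rec <- trace_record(x, rest = c(0, 1))
  expect_equal(estimate_threshold(rec, "LTA", highpass_hz = NULL), 0.10)

  expect_error(estimate_threshold(trace_record(numeric(10000)), "LTA",
                                  highpass_hz = NULL),
               "zero background")

  # white noise: rectified mean is sigma * sqrt(2/pi) (half-normal)
  set.seed(1)
  sigma <- 0.05
  xw <- rnorm(5 * 10000, 0, sigma)
  thr <- estimate_threshold(trace_record(xw, rest = c(0, 5)), "LTA",
                            highpass_hz = NULL)
  expect_equal(thr, 5 * sigma * sqrt(2 / pi), tolerance = 0.02)
})

test_that("threshold scales linearly and spike count is monotone in it", {
  em <- gen_emg(n_cycles = 5, seed = 3)
  thr <- estimate_threshold(em$record, "LTA")
  n0 <- length(extract_spikes(em$record, "LTA", thr)$spike_times_s)
  rec2 <- emg_record(lapply(em$record$channels, `*`, 3.7),
                     em$record$sample_rate, em$record$rest_interval)
  thr2 <- estimate_threshold(rec2, "LTA")
  expect_equal(thr2, 3.7 * thr, tolerance = 1e-9)
  expect_equal(length(extract_spikes(rec2, "LTA", thr2)$spike_times_s), n0)
  counts <- vapply(thr * c(0.5, 1, 2, 8, 30), function(th) {
    length(extract_spikes(em$record, "LTA", th)$spike_times_s)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("rendered spikes are recovered at their programmed times", {
  em <- gen_emg(n_cycles = 10, spacing = "regular", seed = 4)
  thr <- estimate_threshold(em$record, "LTA")
  tr <- extract_spikes(em$record, "LTA", thr)
  truth <- em$truth$spike_times$LTA
  expect_equal(length(tr$spike_times_s), length(truth))
  expect_lt(max(abs(tr$spike_times_s - truth)), 5e-4)
  expect_equal(mean(tr$amplitudes_mV), mean(em$truth$spike_amps$LTA),
               tolerance = 0.05)
  # sub-threshold trace: empty train allowed
  quiet <- trace_record(runif(10000, -0.005, 0.005))
  tr0 <- extract_spikes(quiet, "LTA", 0.1, highpass_hz = NULL)
  expect_length(tr0$spike_times_s, 0L)
})

test_that("vectorized spike extraction equals the brute-force scan", {
  set.seed(99)
  fs <- 10000
  for (rep in 1:50) {
    n <- sample(5000:10000, 1)           # traces of 0.5 to 1 s
    x <- runif(n, -0.02, 0.02)
    n_sp <- sample(0:30, 1)
    if (n_sp > 0) {
      at <- sample(seq_len(n - 20), n_sp)
      for (i in at) x[i:(i + 9)] <- x[i:(i + 9)] +
          runif(1, 0.3, 2) * sin(2 * pi * (0:9) / 10)
    }
    thr <- runif(1, 0.05, 0.5)
    got <- extract_spikes(trace_record(x, fs), "LTA", thr,
                          highpass_hz = NULL)
    ora <- naive_spike_scan(x, fs, thr)
    expect_identical(got$spike_times_s, ora$times)
    expect_identical(got$amplitudes_mV, ora$amps)
  }
})

test_that("burst detection finds programmed volleys and integrates amplitude", {
  # two 100-ms volleys at 0.5 s and 1.5 s
  volley <- function(t0) seq(t0, t0 + 0.1, by = 1 / 200)
  tt <- c(volley(0.5), volley(1.5))
  tr <- spike_train("LTA", tt, rep(1, length(tt)))
  bs <- detect_bursts(tr, end_s = 2)
  expect_equal(nrow(bs$bursts), 2L)
  expect_lt(max(abs(bs$bursts$onset_s - c(0.5, 1.5))), 0.020)

  # integral of a constant 0.5 mV trace over a 0.2-s burst
  fs <- 10000
  x <- numeric(2 * fs)
  x[(0.5 * fs + 1):(0.7 * fs)] <- 0.5
  sp <- seq(0.5, 0.699, by = 0.005)
  tr2 <- spike_train("LTA", sp, rep(0.5, length(sp)))
  rec <- trace_record(x, fs)
  bs2 <- detect_bursts(tr2, record = rec, highpass_hz = NULL)
  expect_equal(nrow(bs2$bursts), 1L)
  expect_equal(bs2$bursts$integrated_amplitude, 0.1, tolerance = 0.002)

  # alternating generator: one flexor burst per cycle
  em <- gen_emg(n_cycles = 20, seed = 5)
  thr <- estimate_threshold(em$record, "LTA")
  sp20 <- extract_spikes(em$record, "LTA", thr)
  b20 <- detect_bursts(sp20, record = em$record)
  expect_equal(nrow(b20$bursts), 20L)
  expect_lt(max(abs(b20$bursts$onset_s - em$truth$flexor_bursts$onset_s)),
            0.025)
})

test_that("step cycles from flexor onsets split into five exact epochs", {
  bs <- manual_bursts(c(0, 0.5), c(0.2, 0.7))
  part <- segment_cycles(bs)
  expect_equal(nrow(part$cycles), 1L)
  expect_equal(part$epoch_breaks[1, ], seq(0, 0.5, by = 0.1))

  part2 <- segment_cycles(manual_bursts(c(0, 0.5, 1.0), c(0.2, 0.7, 1.2)))
  expect_equal(part2$cycles$end_s - part2$cycles$start_s, c(0.5, 0.5))
  expect_error(segment_cycles(manual_bursts(0, 0.2)), "cannot form cycles")

  # epoch tiling at machine precision, irregular cycles
  part3 <- segment_cycles(manual_bursts(c(0.13, 0.57, 1.219),
                                        c(0.2, 0.7, 1.3)))
  durs <- part3$cycles$end_s - part3$cycles$start_s
  sums <- rowSums(part3$epoch_breaks[, -1] - part3$epoch_breaks[, -6])
  expect_identical(sums, durs)
  expect_identical(part3$epoch_breaks[, 6], part3$cycles$end_s)

  # programmed 2.5 Hz stepping
  em <- gen_emg(n_cycles = 15, seed = 6)
  thr <- estimate_threshold(em$record, "LTA")
  b <- detect_bursts(extract_spikes(em$record, "LTA", thr),
                     record = em$record)
  cyc <- segment_cycles(b)
  expect_equal(mean(cyc$cycles$end_s - cyc$cycles$start_s), 0.4,
               tolerance = 0.02)
})

test_that("flexor/extensor overlap measures co-activation", {
  f <- manual_bursts(c(0, 1), c(0.4, 1.4))
  e_disjoint <- manual_bursts(c(0.4, 1.4), c(1.0, 2.0))
  expect_equal(burst_alternation(f, e_disjoint)$overlap_fraction, c(0, 0))
  e_same <- manual_bursts(c(0, 1), c(0.4, 1.4))
  expect_equal(burst_alternation(f, e_same)$overlap_fraction, c(1, 1))

  # programmed 30% co-activation, measured on truth envelopes
  em <- gen_emg(n_cycles = 20, coactivation_fraction = 0.3, seed = 7)
  fx <- with(em$truth$flexor_bursts, manual_bursts(onset_s, offset_s))
  ex <- with(em$truth$extensor_bursts, manual_bursts(onset_s, offset_s))
  ov <- burst_alternation(fx, ex)
  expect_equal(mean(ov$overlap_fraction), 0.30, tolerance = 0.05)
})

test_that("spike recovery holds at high signal-to-noise ratio", {
  em <- gen_emg(n_cycles = 10, amp_mean_mV = 1, noise_sd_mV = 0.1,
                seed = 8)
  thr <- estimate_threshold(em$record, "LTA")
  tr <- extract_spikes(em$record, "LTA", thr)
  truth <- em$truth$spike_times$LTA
  matched <- vapply(truth, function(s) {
    any(abs(tr$spike_times_s - s) < 0.001)
  }, logical(1))
  expect_gte(mean(matched), 0.99)
  spurious <- vapply(tr$spike_times_s, function(s) {
    !any(abs(truth - s) < 0.001)
  }, logical(1))
  expect_lte(mean(spurious), 0.01)
})
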