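test_that("knee triangulation solves the two-circle geometry", {
  segs <- segment_lengths(3, 4)
  # 3-4-5 right triangle, rostral branch
  k <- infer_knee(c(0, 0), c(5, 0), segs)
  expect_equal(k$point, c(1.8, 2.4), tolerance = 1e-12)
  expect_false(k$degraded)
  # caudal branch mirrors across the chord
  expect_equal(infer_knee(c(0, 0), c(5, 0), segs, side = "caudal")$point,
               c(1.8, -2.4), tolerance = 1e-12)
  # fully extended limb: knee on the segment
  k2 <- infer_knee(c(0, 0), c(0, -7), segs)
  expect_equal(k2$point, c(0, -3), tolerance = 1e-9)
  expect_false(k2$degraded)
  # non-intersecting circles: proportional projection, flagged
  k3 <- infer_knee(c(0, 0), c(10, 0), segs)
  expect_equal(k3$point, c(30 / 7, 0), tolerance = 1e-12)
  expect_true(k3$degraded)
  expect_error(infer_knee(c(1, 2), c(1, 2), segs), "degenerate")
})

test_that("forward-kinematics round trip recovers knee and angles", {
  n <- 300
  p <- random_poses(n, seed = 101)
  mk <- pose_markers(p$hip, p$knee, p$ankle, p$segs)
  # per-pose triangulation against the true knee marker
  for (i in seq_len(n)) {
    hip <- c(mk$hip_x[i], mk$hip_y[i])
    ankle <- c(mk$ankle_x[i], mk$ankle_y[i])
    knee <- c(mk$knee_x[i], mk$knee_y[i])
    got <- infer_knee(hip, ankle, p$segs, side = knee_branch(hip, ankle, knee))
    expect_false(got$degraded)
    expect_lt(sqrt(sum((got$point - knee)^2)), 1e-9)
  }
  # angle recovery with the knee marker present
  ms <- marker_series(mk, frame_rate = 250)
  ang <- compute_joint_angles(ms, segs = p$segs)
  expect_lt(max(abs(ang$hip_deg - p$hip)), 1e-6)
  expect_lt(max(abs(ang$knee_deg - p$knee)), 1e-6)
  expect_lt(max(abs(ang$ankle_deg - p$ankle)), 1e-6)
})

test_that("knee-absent angle computation matches the knee-present one", {
  n <- 200
  p <- random_poses(n, seed = 102)
  mk <- pose_markers(p$hip, p$knee, p$ankle, p$segs)
  rostral <- vapply(seq_len(n), function(i) {
    knee_branch(c(mk$hip_x[i], mk$hip_y[i]), c(mk$ankle_x[i], mk$ankle_y[i]),
                c(mk$knee_x[i], mk$knee_y[i])) == "rostral"
  }, logical(1))
  mk <- mk[rostral, ]
  expect_gt(nrow(mk), 50)
  with_knee <- compute_joint_angles(marker_series(mk, 250), segs = p$segs)
  mk2 <- mk
  mk2$knee_x <- mk2$knee_y <- NULL
  without <- compute_joint_angles(marker_series(mk2, 250), segs = p$segs)
  for (j in c("hip_deg", "knee_deg", "ankle_deg")) {
    expect_lt(max(abs(with_knee[[j]] - without[[j]])), 1e-6)
  }
})

test_that("collinear segments give straight joint angles", {
  co <- data.frame(iliac_crest_x = 0, iliac_crest_y = 1,
                   hip_x = 0, hip_y = 0,
                   knee_x = 0, knee_y = -1,
                   ankle_x = 0.5, ankle_y = -1.8,
                   toe_x = 1.2, toe_y = -2.1)
  co <- co[rep(1, 10), ]
  ang <- compute_joint_angles(marker_series(co, 250))
  expect_equal(ang$hip_deg, rep(180, 10))
})

test_that("marker gaps interpolate up to the limit and flag beyond it", {
  p <- random_poses(40, seed = 103)
  mk <- pose_markers(p$hip, p$knee, p$ankle, p$segs)
  ref <- compute_joint_angles(marker_series(mk, 250), segs = p$segs)
  mk$toe_x[10:12] <- NA; mk$toe_y[10:12] <- NA      # 3-frame gap: fillable
  mk$ankle_x[25:30] <- NA; mk$ankle_y[25:30] <- NA  # 6-frame gap: not
  ang <- compute_joint_angles(marker_series(mk, 250), segs = p$segs)
  expect_false(any(ang$missing[10:12]))
  expect_true(all(ang$missing[25:30]))
  expect_equal(ang$hip_deg[1:9], ref$hip_deg[1:9])
})

test_that("gait events are recovered from toe contact", {
  fr <- 250
  t <- seq(0, 2.5, by = 1 / fr)
  toe_y <- numeric(length(t))
  lift <- t >= 1.0 & t < 1.3
  # flat-topped lift: fast rise and landing, as a real toe trajectory
  toe_y[lift] <- pmin(1, 10 * sin(pi * (t[lift] - 1.0) / 0.3))
  co <- data.frame(iliac_crest_x = 0, iliac_crest_y = 4, hip_x = 0,
                   hip_y = 3, ankle_x = 0.5, ankle_y = 0.5,
                   toe_x = 1, toe_y = toe_y)
  ev <- detect_gait_events(marker_series(co, fr))
  expect_equal(length(ev$swing_onsets), 1L)
  expect_equal(ev$swing_onsets[1], 1.00, tolerance = 1 / fr + 1e-9)
  expect_equal(ev$stance_onsets[length(ev$stance_onsets)], 1.30,
               tolerance = 1 / fr + 1e-9)

  co$toe_y <- 0
  expect_warning(ev0 <- detect_gait_events(marker_series(co, fr)),
                 "no gait events")
  expect_length(ev0$stance_onsets, 0L)
})

test_that("programmed cycles are recovered by event detection", {
  g <- gen_gait(n_cycles = 11, seed = 21)
  ev <- detect_gait_events(g$markers)
  # the stance onset at the very first frame is undetectable
  expect_equal(length(ev$stance_onsets), 10L)
  expect_equal(ev$stance_onsets, g$events$stance_onsets[2:11],
               tolerance = 1 / 250 + 1e-9)
  truth_sw <- g$events$swing_onsets
  detect_sw <- ev$swing_onsets[-1]
  expect_lt(max(abs(detect_sw - truth_sw[2:11])), 2 / 250 + 1e-9)
  # duty factor within 5% relative of the programmed stance fraction
  duty <- (ev$swing_onsets[-1] - ev$stance_onsets) /
    diff(c(ev$stance_onsets, g$events$stance_onsets[11] + 0.4))
  expect_lt(abs(mean(duty) - 0.6), 0.02)
})

test_that("cycle normalization is linear, exact and idempotent", {
  fr <- 250
  n <- 100
  t <- (seq_len(n + 10) - 1) / fr
  T_cyc <- n / fr
  u_frame <- pmin(t / T_cyc, 1)
  ramp <- 10 + 5 * t / T_cyc
  ang <- make_angles(ramp, ramp, ramp, frame_rate = fr)
  ev <- gait_events(c(0, T_cyc), numeric(0), source = "manual")
  ens <- normalize_cycles(ang, ev)
  u_out <- seq(0, 1, length.out = 512)
  u_max <- (n - 1) / fr / T_cyc
  expected <- 10 + 5 * pmin(u_out, u_max)   # clamped linear ramp
  expect_equal(as.numeric(ens$cycles$hip[1, ]), expected, tolerance = 1e-12)

  # identical cycles: per-bin SD and CV are zero
  g <- gen_gait(n_cycles = 6, mode = "template", seed = 5)
  e2 <- normalize_cycles(g$angles, g$events)
  expect_lt(max(e2$sd$hip), 1e-10)
  expect_lt(max(e2$cv$hip, na.rm = TRUE), 1e-12)

  # idempotence: renormalizing a 512-sample cycle reproduces it
  prof <- as.numeric(e2$mean$hip)
  t512 <- seq(0, 1, length.out = 512) * 0.4
  ang512 <- make_angles(prof, prof, prof, time_s = t512)
  ev512 <- gait_events(c(0, 0.4), numeric(0), source = "manual")
  # include the final sample in the cycle span
  ev512$stance_onsets[2] <- 0.4 + 1e-6
  e3 <- normalize_cycles(ang512, ev512)
  expect_equal(as.numeric(e3$cycles$hip[1, ]), prof, tolerance = 1e-6)
})

test_that("swing onset bin sits at the hip-angle maximum", {
  fr <- 250
  n_cyc <- 4
  t <- seq(0, n_cyc * 0.4 - 1 / fr, by = 1 / fr)
  u <- (t %% 0.4) / 0.4
  hip <- 100 + 20 * cos(2 * pi * (u - 0.6))  # peak at 60% of the cycle
  ang <- make_angles(hip, frame_rate = fr)
  ev <- gait_events(seq(0, n_cyc) * 0.4, numeric(0), source = "manual")
  ens <- normalize_cycles(ang, ev)
  expect_lte(abs(ens$swing_start_bin - round(0.6 * 512)), 1)
})

test_that("per-bin CV is scale invariant and tracks programmed jitter", {
  g <- gen_gait(n_cycles = 20, mode = "template", swing_jitter_sd = 0.05,
                seed = 31)
  ens <- normalize_cycles(g$angles, g$events)
  cv <- swing_cv(ens, "hip")
  expect_equal(mean(cv$pooled), 0.05, tolerance = 0.05)
  # scaling all cycles leaves the CV unchanged
  ang2 <- g$angles
  for (j in c("hip_deg", "knee_deg", "ankle_deg")) ang2[[j]] <- 3 * ang2[[j]]
  cv2 <- swing_cv(normalize_cycles(ang2, g$events), "hip")
  expect_equal(cv2$pooled, cv$pooled, tolerance = 1e-10)
  expect_error(swing_cv(structure(list(n_cycles = 1), class = "cycle_ensemble")),
               "variability undefined")
})

test_that("doubling swing jitter separates pooled CV distributions", {
  ga <- gen_gait(n_cycles = 20, mode = "template", swing_jitter_sd = 0.05,
                 seed = 32)
  gb <- gen_gait(n_cycles = 20, mode = "template", swing_jitter_sd = 0.10,
                 seed = 33)
  cva <- swing_cv(normalize_cycles(ga$angles, ga$events), "hip")$pooled
  cvb <- swing_cv(normalize_cycles(gb$angles, gb$events), "hip")$pooled
  expect_lt(mean(cva), mean(cvb))
  p <- stats::wilcox.test(cva, cvb)$p.value
  expect_lt(p, 0.05)
})

test_that("intralimb coupling recovers programmed phase lags", {
  g <- gen_gait(n_cycles = 20, mode = "template", seed = 41)
  cp <- intralimb_coupling(g$angles, g$events)
  expect_equal(cp$circular_mean_phase, 0.25, tolerance = 0.01)
  expect_gt(cp$resultant_R, 0.99)

  # identical joints: zero phase, perfect concentration
  cp0 <- intralimb_coupling(g$angles, g$events, joint_a = "hip",
                            joint_b = "hip")
  expect_equal(cp0$circular_mean_phase, 0, tolerance = 1e-9)
  expect_equal(cp0$resultant_R, 1, tolerance = 1e-12)

  # translation invariance of phases and R
  ang_sh <- g$angles
  ang_sh$time_s <- ang_sh$time_s + 17.3
  ev_sh <- gait_events(g$events$stance_onsets + 17.3,
                       g$events$swing_onsets + 17.3, source = "manual")
  cps <- intralimb_coupling(ang_sh, ev_sh)
  expect_equal(cps$phases, cp$phases, tolerance = 1e-9)
  expect_equal(cps$resultant_R, cp$resultant_R, tolerance = 1e-12)
})

test_that("uniform per-cycle lags give near-zero resultant", {
  set.seed(7)
  fr <- 250
  n_cyc <- 1000
  frames <- 50
  peaks <- runif(n_cyc)                      # uniform ankle peak phase
  u <- rep(seq(0, 1 - 1 / frames, length.out = frames), n_cyc)
  cyc <- rep(seq_len(n_cyc), each = frames)
  hip <- 100 + 20 * cos(2 * pi * (u - 0.3))
  ankle <- 100 + 20 * cos(2 * pi * (u - peaks[cyc]))
  ang <- make_angles(hip, hip, ankle, frame_rate = fr)
  ev <- gait_events(seq(0, n_cyc) * frames / fr, numeric(0),
                    source = "manual")
  cp <- intralimb_coupling(ang, ev)
  expect_equal(cp$n_cycles, n_cyc)
  expect_lt(cp$resultant_R, 0.1)
  # flat cycles are skipped and counted
  ang$ankle_deg[1:frames] <- 90
  cp2 <- intralimb_coupling(ang, ev)
  expect_equal(cp2$n_skipped, 1L)
})

test_that("interlimb coupling reads alternation and degrades with jitter", {
  ref_on <- seq(0, 10, by = 0.5)
  ref <- gait_events(ref_on, numeric(0), source = "manual")
  # strict alternation: contact at mid-cycle
  alt <- gait_events(ref_on + 0.25, numeric(0), source = "manual")
  cp <- interlimb_coupling(ref, alt)
  expect_equal(cp$circular_mean_phase, 0.5, tolerance = 1e-9)
  expect_equal(cp$resultant_R, 1, tolerance = 1e-12)
  # synchrony: phase zero
  sync <- gait_events(ref_on + 1e-6, numeric(0), source = "manual")
  cps <- interlimb_coupling(ref, sync)
  expect_equal(cps$circular_mean_phase, 0, tolerance = 1e-4)
  # resultant decreases monotonically with circular jitter
  set.seed(11)
  e <- rnorm(length(ref_on))
  e <- (e - mean(e)) / sd(e)
  rs <- vapply(c(0.02, 0.1, 0.2), function(sig) {
    oth <- gait_events(sort(ref_on + 0.25 + 0.5 * sig * e), numeric(0),
                       source = "manual")
    interlimb_coupling(ref, oth)$resultant_R
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("swim strokes tile the hip-angle oscillation", {
  tt <- seq(0, 2, by = 1 / 250)
  tt <- tt[tt < 2]
  hip <- 100 + 20 * sin(2 * pi * 3 * tt)
  st <- segment_swim_strokes(hip, 250)
  expect_equal(nrow(st$power_strokes), 6L)
  expect_equal(nrow(st$return_strokes), 6L)
  expect_equal(st$swim_frequency_hz, 3, tolerance = 0.01)
  # alternation and tiling between consecutive strokes
  segs <- rbind(cbind(st$power_strokes$start_s, st$power_strokes$end_s),
                cbind(st$return_strokes$start_s, st$return_strokes$end_s))
  segs <- segs[order(segs[, 1]), ]
  expect_true(all(segs[, 2] > segs[, 1]))
  expect_equal(segs[-1, 1], segs[-nrow(segs), 2], tolerance = 1e-9)

  expect_error(segment_swim_strokes(seq(0, 100, length.out = 250), 250),
               "no strokes")
})

test_that("swim frequency is recovered under cycle jitter", {
  sw <- gen_swim(frequency_hz = 3, n_cycles = 10, jitter_sd = 0, seed = 1)
  st <- segment_swim_strokes(sw$hip_deg, sw$frame_rate)
  expect_equal(st$swim_frequency_hz, 3, tolerance = 0.01)
  swj <- gen_swim(frequency_hz = 4, n_cycles = 30, jitter_sd = 0.10,
                  seed = 2)
  stj <- segment_swim_strokes(swj$hip_deg, swj$frame_rate)
  expect_equal(stj$swim_frequency_hz, 4, tolerance = 4 * 0.05)
})

test_that("gait metrics recover the programmed toe program", {
  g <- gen_gait(n_cycles = 8, stride_length_cm = 6, step_height_cm = 0.8,
                seed = 51)
  gm <- gait_metrics(g$markers, g$events, segs = segment_lengths(1.55, 1.85))
  expect_equal(gm$per_cycle$stride_length_cm, rep(6, 8), tolerance = 1e-9)
  expect_equal(gm$per_cycle$step_height_cm, rep(0.8, 8), tolerance = 0.02)
  expect_equal(gm$step_frequency_hz, 2.5, tolerance = 1e-9)
  expect_true(all(gm$per_cycle$hip_excursion_deg ==
                  pmax(gm$per_cycle$hip_excursion_deg, 0)))
  # constant crest height normalizes to exactly 1 over any baseline
  gm2 <- gait_metrics(g$markers, g$events,
                      segs = segment_lengths(1.55, 1.85),
                      baseline_window = c(0, 1))
  expect_equal(unique(gm2$iliac_crest_height$normalized), 1)
})
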