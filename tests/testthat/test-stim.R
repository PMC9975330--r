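test_that("peristimulus windows count spikes before and after the pulse", {
  on <- 2.0
  st <- spike_train("LTA", on + c(-0.030, -0.010, 0.020, 0.030, 0.040),
                    amplitudes_mV = c(1, 2, 3, 4, 5))
  w <- pulse_window_counts(st, on)
  expect_equal(w$pre_count, 2L)
  expect_equal(w$post_count, 3L)
  expect_equal(w$pre_mean_amp, 1.5)
  expect_equal(w$post_mean_amp, 4)
  expect_false(w$excluded)
  # empty train
  w0 <- pulse_window_counts(spike_train("LTA", numeric(0), numeric(0)), on)
  expect_equal(c(w0$pre_count, w0$post_count), c(0L, 0L))
  expect_true(is.na(w0$pre_mean_amp) && is.na(w0$post_mean_amp))
  # window past the recording edge is excluded
  we <- pulse_window_counts(st, on, record_span = c(on - 0.04, on + 1))
  expect_true(we$excluded)
})

test_that("response classification follows the sign of the count change", {
  expect_equal(classify_response(4, 7), "excitatory")
  expect_equal(classify_response(6, 2), "inhibitory")
  expect_equal(classify_response(5, 5), "failure")
  expect_equal(classify_response(5, 6, tolerance = 1), "failure")
  # antisymmetry: swapping pre and post flips the label
  set.seed(2)
  pre <- rpois(200, 5); post <- rpois(200, 5)
  a <- classify_response(pre, post)
  b <- classify_response(post, pre)
  expect_identical(b[a == "excitatory"],
                   rep("inhibitory", sum(a == "excitatory")))
  expect_identical(b[a == "inhibitory"],
                   rep("excitatory", sum(a == "inhibitory")))
  expect_identical(b[a == "failure"], rep("failure", sum(a == "failure")))
})

test_that("pulses are assigned to epochs by cycle fraction", {
  part <- segment_cycles(manual_bursts(c(0, 1), c(0.3, 1.3)))
  expect_equal(assign_pulse_phase(0.15, part),
               list(epoch = 1L, phase = "swing", cycle = 1L))
  expect_equal(assign_pulse_phase(0.70, part)$epoch, 4L)
  expect_equal(assign_pulse_phase(0.70, part)$phase, "stance")
  # boundary at 0.4 of the cycle belongs to epoch 3 (half-open)
  expect_equal(assign_pulse_phase(0.40, part)$epoch, 3L)
  expect_true(is.na(assign_pulse_phase(2.5, part)$epoch))
})

test_that("session summaries report label proportions per stratum", {
  resp <- data.frame(
    pulse_time_s = 1:10, pre_count = 5,
    post_count = c(rep(8, 5), rep(2, 3), rep(5, 2)),
    delta_density = c(rep(3, 5), rep(-3, 3), rep(0, 2)),
    pre_mean_amp_mV = 1, post_mean_amp_mV = 1.2,
    label = c(rep("excitatory", 5), rep("inhibitory", 3),
              rep("failure", 2)),
    epoch = 1L, phase = "swing", muscle = "LTA", excluded = FALSE)
  s <- summarize_session(resp)$strata
  expect_equal(s$proportion_excitatory, 0.5)
  expect_equal(s$proportion_inhibitory, 0.3)
  expect_equal(s$proportion_failure, 0.2)
  expect_equal(s$n_pulses, 10L)
  expect_lt(abs(s$proportion_excitatory + s$proportion_inhibitory +
                s$proportion_failure - 1), 1e-9)
  # all failures
  resp$label <- "failure"; resp$delta_density <- 0; resp$post_count <- 5
  s2 <- summarize_session(resp)$strata
  expect_equal(c(s2$proportion_excitatory, s2$proportion_inhibitory,
                 s2$proportion_failure), c(0, 0, 1))
  # invariance to pulse order and uniform time shift
  perm <- resp[sample(nrow(resp)), ]
  perm$pulse_time_s <- perm$pulse_time_s + 1000
  expect_equal(summarize_session(perm)$strata, s2)
})

test_that("programmed deterministic effects are recalled perfectly", {
  labs <- rep(c("excitatory", "inhibitory", "failure"), each = 50)
  es <- gen_emg(channels = "LTA", spacing = "regular",
                stim = list(n_pulses = 150, labels = labs,
                            effect_size = 2), seed = 71)
  thr <- estimate_threshold(es$record, "LTA")
  tr <- extract_spikes(es$record, "LTA", thr)
  span <- c(0, es$record$n_samples / es$record$sample_rate)
  resp <- pulse_responses(tr, es$protocol, record_span = span)
  expect_false(any(resp$excluded))
  expect_identical(resp$label, labs)
  # mean density change equals the programmed effect size
  expect_equal(mean(resp$delta_density[labs == "excitatory"]), 2)
  expect_equal(mean(resp$delta_density[labs == "inhibitory"]), -2)
})

test_that("a stochastic response mixture is recovered within binomial error", {
  mix <- c(excitatory = 0.6, inhibitory = 0.25, failure = 0.15)
  es <- gen_emg(channels = "LTA", spacing = "regular",
                stim = list(n_pulses = 150, mixture = mix), seed = 72)
  thr <- estimate_threshold(es$record, "LTA")
  tr <- extract_spikes(es$record, "LTA", thr)
  span <- c(0, es$record$n_samples / es$record$sample_rate)
  resp <- pulse_responses(tr, es$protocol, record_span = span)
  s <- summarize_session(resp)$strata
  n <- s$n_pulses
  # recovery against the realized per-pulse truth is within binomial error
  truth_prop <- table(factor(es$truth$pulse_labels,
                             levels = names(mix))) / n
  for (lab in names(mix)) {
    phat <- s[[paste0("proportion_", lab)]]
    half <- 1.96 * sqrt(mix[[lab]] * (1 - mix[[lab]]) / n)
    expect_lt(abs(phat - truth_prop[[lab]]), half + 1e-12)
  }
  # the generator draw itself is consistent with the programmed mixture
  gof <- stats::chisq.test(table(factor(es$truth$pulse_labels,
                                        levels = names(mix))),
                           p = mix)
  expect_gt(gof$p.value, 0.001)
  # detected labels equal programmed labels pulse by pulse
  expect_identical(resp$label, es$truth$pulse_labels)
})

test_that("train pulses with colliding windows are excluded", {
  onsets <- seq(1, 1.98, by = 0.02)   # 50 Hz train
  proto <- stim_protocol(onsets, mode = "train", train_frequency_hz = 50,
                         train_duration_s = 1)
  st <- spike_train("LTA", seq(0.5, 2.5, by = 0.01),
                    rep(1, 201))
  resp <- pulse_responses(st, proto, record_span = c(0, 3))
  expect_true(all(resp$excluded))
  expect_error(summarize_session(resp), "no included pulses")
})

test_that("null stimulation yields symmetric excitatory/inhibitory rates", {
  es <- gen_emg(channels = "LTA", spacing = "poisson",
                stim = list(n_pulses = 150, labels = rep("failure", 150),
                            background_rate_hz = 100), seed = 73)
  thr <- estimate_threshold(es$record, "LTA")
  tr <- extract_spikes(es$record, "LTA", thr)
  span <- c(0, es$record$n_samples / es$record$sample_rate)
  s <- summarize_session(pulse_responses(tr, es$protocol,
                                         record_span = span))$strata
  # under a stationary rate the two active labels are symmetric
  expect_lt(abs(s$proportion_excitatory - s$proportion_inhibitory),
            2 * sqrt(0.5 * 0.5 / s$n_pulses) * 2)
})

test_that("response metrics correlate with the locomotor score", {
  r1 <- score_response_correlation(c(2, 8, 14, 20), c(0.1, 0.3, 0.5, 0.7))
  expect_equal(r1$r, 1, tolerance = 1e-9)
  expect_equal(r1$slope, 0.1 / 3, tolerance = 1e-9)
  r2 <- score_response_correlation(c(2, 8, 14, 20), rep(0.4, 4))
  expect_equal(r2$slope, 0)
  expect_true(is.na(r2$r))
  expect_match(r2$note, "zero variance")
  expect_error(score_response_correlation(c(1, 2), c(0, 1)))

  # slope recovery: failure proportion declining with score
  set.seed(12)
  hits <- 0L
  for (rep in 1:200) {
    score <- sample(0:20, 10, replace = TRUE)
    prop <- 0.8 - 0.03 * score + rnorm(10, 0, 0.05)
    fit <- stats::lm(prop ~ score)
    ci <- stats::confint(fit)["score", ]
    if (ci[1] <= -0.03 && -0.03 <= ci[2]) hits <- hits + 1L
    r <- score_response_correlation(score, prop)
    if (rep == 1L) expect_equal(r$slope, unname(coef(fit)[2]))
  }
  expect_gte(hits / 200, 0.90)
})
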