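test_that("pulse trains have the right number of rising edges and spacing", {
  fs <- 1000
  for (np in c(1, 5, 20, 30)) {
    v <- make_pulse_train(stim_protocol(np), fs, 16)
    edges <- which(diff(c(0L, v)) == 1L)
    expect_length(edges, np)
    if (np > 1)
      expect_true(all(abs(diff(edges) / fs - 1 / 30) <= 1.5 / fs))
  }
  # a 30-pulse 30 Hz train spans (29/30 + 0.002) s
  v <- make_pulse_train(stim_protocol(30), fs, 16)
  on <- range(which(v == 1L))
  expect_equal(diff(on) / fs, 29 / 30 + 0.002, tolerance = 2 / fs)
})

test_that("undersampled or overflowing pulse trains are rejected", {
  expect_error(make_pulse_train(stim_protocol(5), 10, 16), "undersamples")
  expect_error(make_pulse_train(stim_protocol(30, onset_time = 15.5), 1000, 16),
               "overflow")
  expect_silent(make_pulse_train(stim_protocol(1), 10, 16))
})

test_that("a non-responding class yields a flat noiseless trace", {
  cls <- response_class("none", baseline_level = 0.3, baseline_drift_sd = 0,
                        noise_sd = 0)
  r <- simulate_repeat(cls, stim_protocol(20), seed = 1)
  expect_equal(r$values, rep(0.3, length(r$time)))
})

test_that("noiseless excitation peaks after onset and decays exponentially", {
  cls <- response_class("strong_excitation", peak_amplitude = 1, rise_tau = 0.1,
                        decay_tau = 1, reliability = 1,
                        baseline_drift_sd = 0, noise_sd = 0)
  pr <- stim_protocol(20)
  r <- simulate_repeat(cls, pr, sampling_rate = 20, seed = 1)
  ipk <- which.max(r$values)
  expect_gt(r$time[ipk], pr$onset_time)
  expect_equal(max(r$values), 1, tolerance = 1e-6)
  # well after the peak the decay is a single exponential with decay_tau
  tail_idx <- which(r$time > r$time[ipk] + 1 & r$values > 1e-4)
  ratios <- r$values[tail_idx + 1] / r$values[tail_idx]
  expect_equal(ratios, rep(exp(-0.05 / 1), length(ratios)), tolerance = 0.01)
})

test_that("inhibition from an elevated baseline dips to the planted extremum", {
  # analytic: the normalized summed kernel has extremum 1, so the noiseless
  # trace minimum is baseline + amplitude, up to sampling of the peak
  cls <- response_class("inhibition", peak_amplitude = -0.8,
                        baseline_level = 1, baseline_drift_sd = 0, noise_sd = 0)
  r <- simulate_repeat(cls, stim_protocol(20), sampling_rate = 100, seed = 1)
  expect_equal(min(r$values), 0.2, tolerance = 0.02)
  expect_gt(min(which(r$values < 0.9)) / 100, 5)  # dip starts after onset
})

test_that("rebound responses appear after train offset plus one decay tau", {
  cls <- response_class("rebound", peak_amplitude = 0.8, decay_tau = 1,
                        reliability = 1, baseline_drift_sd = 0, noise_sd = 0)
  pr <- stim_protocol(20)
  r <- simulate_repeat(cls, pr, sampling_rate = 20, seed = 1)
  t_off <- pr$onset_time + train_duration(pr)
  expect_true(all(r$values[r$time <= t_off + 1] < 0.5))
  expect_equal(max(r$values), 0.8, tolerance = 1e-6)
})

test_that("repeat peak matches the waveform extremum within one sampling interval", {
  pr <- stim_protocol(5)
  for (kind in c("strong_excitation", "weak_excitation", "inhibition")) {
    cls <- response_class(kind, reliability = 1, baseline_drift_sd = 0,
                          noise_sd = 0)
    r <- simulate_repeat(cls, pr, sampling_rate = 10, seed = 3)
    w <- response_waveform(cls, pr, seq(0, 16, by = 0.001))
    planted <- cls$baseline_level + w[which.max(abs(w))]
    observed <- r$values[which.max(abs(r$values - cls$baseline_level))]
    # sampled extremum can undershoot by at most the kernel change over 0.1 s
    expect_lt(abs(observed - planted), 0.1)
  }
})

test_that("response class invariants are enforced", {
  expect_error(response_class("inhibition", baseline_level = 0), "baseline")
  expect_error(response_class("inhibition", peak_amplitude = 0.5), "negative")
  expect_error(response_class("none", reliability = 1.5))
})

test_that("experiment simulation counts and determinism hold", {
  gt <- null_connectome(2)
  ds <- simulate_experiment(gt, n_flies = 6, protocols = default_protocols(),
                            seed = 7)
  expect_equal(nrow(ds$runs), 2 * 6 * 5)
  expect_equal(sum(vapply(ds$traces, ncol, 0L)), 2 * 6 * 5 * 4)
  ds2 <- simulate_experiment(gt, n_flies = 6, protocols = default_protocols(),
                             seed = 7)
  expect_identical(ds$traces, ds2$traces)
  expect_identical(ds$runs, ds2$runs)
  ds3 <- simulate_experiment(gt, n_flies = 6, protocols = default_protocols(),
                             seed = 8)
  expect_false(identical(ds$traces, ds3$traces))
})

test_that("planted responses on non-overlapping pairs are rejected", {
  expect_error(
    connectome(c("SMP.b-LAL.s", "WED.b-BU.s"),
               data.frame(pre = "SMP.b-LAL.s", post = "WED.b-BU.s",
                          kind = "strong_excitation")),
    "non-overlapping")
  expect_error(simulate_experiment(null_connectome(0)), "empty")
})

test_that("synthetic movies encode the trace, the drift and the mask", {
  tr <- rep(c(0, 1), each = 5)
  mv <- simulate_movie(tr, frame_shape = c(24, 24), roi_radius = 5,
                       drift = c(0, 0), noise_scale = 0, seed = 1)
  avg <- apply(mv$frames, c(2, 3), mean)
  expect_length(unique(round(as.vector(avg), 6)), 2)  # two-level image
  expect_identical(mv$shift, c(2, -3) * 0)
  mv2 <- simulate_movie(tr, frame_shape = c(24, 24), roi_radius = 5,
                        drift = c(2, -3), noise_scale = 0, seed = 1)
  expect_identical(mv2$shift, c(2, -3))
  expect_error(simulate_movie(tr, frame_shape = c(24, 24), roi_radius = 5,
                              drift = c(20, 0)), "out of the")
})
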