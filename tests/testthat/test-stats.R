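time_grid <- seq(0, 15.9, by = 0.1)

test_that("closed-form exponential transient gives Fpeak 1 and tau_half ln 2", {
  v <- ifelse(time_grid < 5, 0, exp(-(time_grid - 5)))
  st <- repeat_stats(v, time_grid, onset = 5)
  expect_equal(st$Fpeak, 1)
  expect_equal(st$Tpeak, 0)
  expect_equal(st$Fbase, 0)
  expect_equal(st$ItoPeak, 0)                     # peak at onset: empty integral
  expect_lt(abs(st$tau_half - log(2)), 0.1)       # within one sampling interval
})

test_that("flat traces give all-zero statistics with undefined tau_half", {
  st <- repeat_stats(rep(0, length(time_grid)), time_grid, onset = 5)
  expect_equal(st$Fpeak, 0)
  expect_equal(st$ItoPeak, 0)
  expect_equal(st$Fbase, 0)
  expect_true(is.na(st$tau_half))
})

test_that("inhibition yields a negative excursion and negative integral", {
  cls <- response_class("inhibition", peak_amplitude = -0.8,
                        baseline_level = 1, baseline_drift_sd = 0, noise_sd = 0)
  r <- simulate_repeat(cls, stim_protocol(20), seed = 1)
  st <- repeat_stats(r$values, r$time, onset = 5)
  expect_equal(st$Fbase, 1)
  expect_equal(st$Fpeak, 0.2, tolerance = 0.05)
  expect_lt(st$ItoPeak, 0)
  expect_lt(st$ItoPeak_norm, 0)
})

test_that("baseline floor binds for near-zero baselines", {
  v <- ifelse(time_grid < 5, 0, exp(-(time_grid - 5)))
  st <- repeat_stats(v, time_grid, onset = 5, fbase_floor = 0.05)
  expect_true(st$floor_bound)
  expect_equal(st$Fpeak_norm, 1 / 0.05)
  st2 <- repeat_stats(v + 1, time_grid, onset = 5)
  expect_false(st2$floor_bound)
  expect_equal(st2$Fpeak_norm, 2)
})

test_that("run medians and within-run correlation behave as specified", {
  # four repeats with planted peak amplitudes 1..4
  shape <- ifelse(time_grid < 5, 0, exp(-(time_grid - 5)))
  traces <- vapply(1:4, function(k) k * shape, numeric(length(time_grid)))
  rs <- run_stats(traces, time_grid, onset = 5)
  expect_equal(rs$Fpeak, 2.5)
  # identical repeats: medians equal repeat values, R_within = 1
  same <- vapply(1:4, function(k) shape, numeric(length(time_grid)))
  rs2 <- run_stats(same, time_grid, onset = 5)
  expect_equal(rs2$Fpeak, 1)
  expect_equal(rs2$R_within, 1)
  expect_warning(run_stats(traces[, 1:3], time_grid, onset = 5), "3 repeats")
})

test_that("two sign-flipped trace pairs give R_within = -1/3", {
  a <- sin(time_grid)
  traces <- cbind(a, a, -a, -a)
  rs <- run_stats(traces, time_grid, onset = 5)
  # six pairwise correlations: two +1, four -1
  expect_equal(rs$R_within, -1 / 3)
})

test_that("pair-level medians and correlations behave as specified", {
  shape <- ifelse(time_grid < 5, 0, exp(-(time_grid - 5)))
  traces <- vapply(1:4, function(k) shape, numeric(length(time_grid)))
  mk_run <- function(fly) cbind(fly = fly, run_stats(traces, time_grid, onset = 5))
  rt <- rbind(mk_run(1), mk_run(2), mk_run(3))
  ps <- pair_stats(rt, list(traces, traces, traces))
  expect_equal(ps$R_between, 1)
  expect_equal(ps$Fpeak, 1)
  # two flies: R_between is the single pairwise correlation
  t2 <- vapply(1:4, function(k) rev(shape), numeric(length(time_grid)))
  ps2 <- pair_stats(rbind(mk_run(1), mk_run(2)), list(traces, t2))
  expect_equal(ps2$R_between, cor(rowMeans(traces), rowMeans(t2)))
  # single fly: undefined correlations
  ps1 <- pair_stats(mk_run(1), list(traces))
  expect_true(is.na(ps1$R_between) && is.na(ps1$R_state))
})

test_that("planted brain-state coupling is detected by R_state", {
  # response amplitude proportional to the fly's baseline level
  pr <- stim_protocol(30)
  flies <- 1:6
  bases <- 0.2 + 0.18 * flies
  rt <- NULL; tl <- list()
  for (f in flies) {
    cls <- response_class("strong_excitation", peak_amplitude = 1.5 * bases[f],
                          baseline_level = bases[f], reliability = 1,
                          baseline_drift_sd = 0.01, noise_sd = 0.02)
    traces <- vapply(1:4, function(r)
      simulate_repeat(cls, pr, seed = 100 * f + r)$values, numeric(160))
    rt <- rbind(rt, cbind(fly = f, run_stats(traces, (0:159) / 10, onset = 5)))
    tl[[f]] <- traces
  }
  ps <- pair_stats(rt, tl)
  expect_gt(ps$R_state, 0.8)
  # oracle: direct correlation of the planted quantities
  expect_gt(cor(bases * 1.5, bases), 0.99)
})

test_that("signed scaling maps batch extrema to +/-1 and matches the explicit rule", {
  expect_equal(scale_signed(c(-2, 1, 4)), c(-1, 0.25, 1))
  expect_equal(scale_signed(c(0, 3)), c(0, 1))
  expect_equal(scale_signed(c(0, 0)), c(0, 0))
  set.seed(9)
  for (k in 1:20) {
    v <- rnorm(30, sd = runif(1, 0.1, 10))
    s <- scale_signed(v)
    oracle <- ifelse(v > 0, v / max(v), ifelse(v < 0, v / abs(min(v)), 0))
    expect_equal(s, oracle)
    expect_true(all(s >= -1 & s <= 1))
    if (any(v > 0)) expect_equal(max(s), 1)
    if (any(v < 0)) expect_equal(min(s), -1)
    expect_equal(scale_signed(s), s)  # idempotent once extrema are +/-1
  }
})

test_that("statistics are invariant to repeat and fly permutation", {
  gt <- null_connectome(3)
  ds <- simulate_experiment(gt, n_flies = 4, protocols = default_protocols(30),
                            seed = 5)
  st <- screen_statistics(ds)
  ds2 <- ds
  # shuffle repeat columns within each run and reverse run order
  set.seed(1)
  ds2$traces <- lapply(ds$traces, function(m) m[, sample(ncol(m))])
  perm <- rev(seq_len(nrow(ds2$runs)))
  ds2$runs <- ds2$runs[perm, ]
  ds2$traces <- ds2$traces[ds2$runs$run_id]
  st2 <- screen_statistics(ds2)
  for (f in c("Fpeak", "ItoPeak", "ItoPeak_norm", "R_within", "R_between"))
    expect_equal(sort(st2$pairs[[f]]), sort(st$pairs[[f]]), tolerance = 1e-12)
})

test_that("pair integral grows with the planted excitatory amplitude", {
  mk <- function(amp) {
    pairs <- data.frame(pre = "FBl2.b-LAL.s", post = "FBl2.s-NO2D.b")
    pairs$class <- list(response_class("strong_excitation", peak_amplitude = amp,
                                       reliability = 1))
    ds <- simulate_experiment(connectome(unlist(pairs[1, 1:2]), pairs),
                              n_flies = 4, protocols = default_protocols(30),
                              seed = 77)
    screen_statistics(ds)$pairs$ItoPeak_norm
  }
  vals <- vapply(c(0.3, 0.6, 1.2, 2.4), mk, numeric(1))
  expect_true(all(diff(vals) >= 0))
})
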