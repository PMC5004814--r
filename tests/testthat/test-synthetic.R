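# Synthetic behavior and spike-train generator.

lib4 <- sequence_library()[c("FFF", "FMS", "SMF", "SSS")]

test_that("psychometric behavior follows mean speed", {
  # slope 0: same right-choice probability for every stimulus (pure bias)
  cfg0 <- session_config(n_trials_per_stimulus = 2000,
                         psychometric = list(slope = 0, midpoint_mm_s = NULL,
                                             lapse = 0, right_bias = 0),
                         seed = 11)
  tr0 <- simulate_behavior(cfg0)
  fr <- tapply(tr0$choice == "right", tr0$stimulus, mean)
  expect_true(all(abs(fr - 0.5) < 0.05))        # binomial noise only
  # steep slope, no lapse: FFF -> right and SSS -> left almost surely
  cfg1 <- session_config(n_trials_per_stimulus = 2500,
                         psychometric = list(slope = 10, midpoint_mm_s = NULL,
                                             lapse = 0, right_bias = 0),
                         seed = 12)
  tr1 <- simulate_behavior(cfg1)
  fr1 <- tapply(tr1$choice == "right", tr1$stimulus, mean)
  expect_gt(fr1["FFF"], 0.99)
  expect_lt(fr1["SSS"], 0.01)
})

test_that("withdrawal times respect the task minimum and target mean", {
  cfg <- session_config(n_trials_per_stimulus = 2500, seed = 13)
  tr <- simulate_behavior(cfg)
  expect_true(all(tr$withdrawal_ms >= 150))
  expect_equal(mean(tr$withdrawal_ms), 190, tolerance = 0.02)
  # right-skew: mean above median
  expect_gt(mean(tr$withdrawal_ms), stats::median(tr$withdrawal_ms))
})

test_that("rate functions have the archetype-defining shapes", {
  fast <- unit_archetype("Fast")
  tr <- unit_rate_function(fast, lib4$FFF)
  # all gains zero -> flat baseline
  flat <- unit_archetype("Fast", velocity_gain = 0, baseline_hz = 5)
  expect_true(all(unit_rate_function(flat, lib4$FFF)$rate_hz == 5))
  # peaks within latency + width of each pulse onset, back to baseline between
  onsets <- pulse_onsets(lib4$FFF)
  for (o in onsets) {
    win <- tr$t_ms >= o & tr$t_ms <= o + fast$kernel_latency_ms +
      3 * fast$kernel_width_ms
    expect_gt(max(tr$rate_hz[win]), fast$baseline_hz + 20)
  }
  between <- tr$t_ms > onsets[2] - 5 & tr$t_ms < onsets[2]
  expect_lt(max(tr$rate_hz[between]), fast$baseline_hz + 2)
  # SlowPos: right-choice rate exceeds left-choice rate late in the trial
  sp <- unit_archetype("SlowPos")
  r_right <- unit_rate_function(sp, lib4$FFF, "right")
  r_left <- unit_rate_function(sp, lib4$FFF, "left")
  late <- r_right$t_ms > 130 & r_right$t_ms < 200
  expect_true(all(r_right$rate_hz[late] - r_left$rate_hz[late] > 5))
  early <- r_right$t_ms < 60
  expect_equal(r_right$rate_hz[early], r_left$rate_hz[early])
  # Medium: suppressed below baseline after pulses; SlowNeg: declining
  med_arch <- unit_archetype("Medium")
  med <- unit_rate_function(med_arch, lib4$FFF)
  expect_lt(min(med$rate_hz), med_arch$baseline_hz - 5)
  sn <- unit_rate_function(unit_archetype("SlowNeg"), lib4$FFF)
  expect_lt(sn$rate_hz[length(sn$rate_hz)], sn$rate_hz[1])
  # rates are clipped at zero
  deep <- unit_rate_function(unit_archetype("Medium", baseline_hz = 2,
                                            suppression_hz = 30), lib4$FFF)
  expect_true(all(deep$rate_hz >= 0))
})

test_that("thinning sampler matches Poisson closed forms", {
  trials <- data.frame(trial_id = 1:10000, stimulus = "FFF",
                       choice = "left", correct = FALSE, withdrawal_ms = 190)
  # lambda == 0 -> no spikes
  silent <- unit_archetype("Unmodulated", baseline_hz = 0)
  expect_equal(nrow(simulate_unit(silent, trials[1:50, ], lib4, seed = 1)), 0)
  # constant 10 Hz over the 275-ms epoch: mean count 2.75, Fano ~ 1
  const <- unit_archetype("Unmodulated", baseline_hz = 10)
  sp <- simulate_unit(const, trials, lib4, seed = 2)
  counts <- tabulate(sp$trial_id, nbins = nrow(trials))
  expect_equal(mean(counts), 2.75, tolerance = 3 * sqrt(2.75 / 1e4) / 2.75)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.06)
  # determinism: same seed gives byte-identical spike tables
  expect_identical(simulate_unit(const, trials[1:100, ], lib4, seed = 7),
                   simulate_unit(const, trials[1:100, ], lib4, seed = 7))
})

test_that("sampler mean count matches the rate-trace integral", {
  fast <- unit_archetype("Fast")
  trace <- unit_rate_function(fast, lib4$FFF)
  expected <- sum((trace$rate_hz[-1] + trace$rate_hz[-length(trace$rate_hz)]) / 2 *
                    diff(trace$t_ms)) / 1000
  n_rep <- 4000
  trials <- data.frame(trial_id = seq_len(n_rep), stimulus = "FFF",
                       choice = "left", correct = FALSE, withdrawal_ms = 190)
  sp <- simulate_unit(fast, trials, lib4, seed = 3)
  counts <- tabulate(sp$trial_id, nbins = n_rep)
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("generated sessions satisfy the schema and are seed-deterministic", {
  cfg <- session_config(n_trials_per_stimulus = 10,
                        units = c(Fast = 2, Medium = 1, SlowPos = 1,
                                  SlowNeg = 1, Unmodulated = 1),
                        seed = 42)
  s1 <- generate_session(cfg)
  expect_s3_class(s1, "session_data")
  expect_silent(validate_session(s1))
  expect_equal(nrow(s1$trials), 40)
  expect_equal(nrow(s1$units), 6)
  expect_true(all(c("depth_um", "width_ms", "snr", "isi_violation",
                    "true_class") %in% names(s1$units)))
  s2 <- generate_session(cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$units, s2$units)
  # unit_spike_list covers every trial, including empty ones
  sl <- unit_spike_list(s1, "u001")
  expect_length(sl, 40)
})

test_that("empirical PSTH of simulated spikes converges to the rate trace", {
  fast <- unit_archetype("Fast")
  trace <- unit_rate_function(fast, lib4$FFF)
  n_rep <- 4000
  trials <- data.frame(trial_id = seq_len(n_rep), stimulus = "FFF",
                       choice = "left", correct = FALSE, withdrawal_ms = 190)
  sp <- simulate_unit(fast, trials, lib4, seed = 5)
  edges <- seq(-25, 250, 5)
  emp <- graphics::hist(sp$time_ms, breaks = edges, plot = FALSE)$counts /
    (n_rep * 5 / 1000)
  theo <- vapply(seq_len(length(edges) - 1), function(i) {
    k <- trace$t_ms >= edges[i] & trace$t_ms < edges[i + 1]
    mean(trace$rate_hz[k])
  }, numeric(1))
  expect_lt(max(abs(emp - theo)), 6)   # Hz; ~4 MC s.e. at the peak bins
})
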