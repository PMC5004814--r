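# PSTHs, temporal-modulation permutation test, evoked metrics, adaptation,
# and choice-related firing.

lib4 <- sequence_library()[c("FFF", "FMS", "SMF", "SSS")]

test_that("PSTH recovers spike counts and smoothing preserves rate mass", {
  empty <- replicate(5, numeric(0), simplify = FALSE)
  p0 <- compute_psth(empty, epoch_ms = c(0, 180))
  expect_true(all(p0$rate_hz == 0))
  # one spike at 7 ms in 1 of 10 trials -> 100 Hz in bin [7, 8)
  sl <- c(list(7), replicate(9, numeric(0), simplify = FALSE))
  p <- compute_psth(sl, bin_ms = 1, epoch_ms = c(0, 180))
  expect_equal(p$rate_hz[8], 100)
  expect_equal(sum(p$rate_hz), 100)
  # boxcar smoothing preserves the time-integral of rate
  ps <- compute_psth(sl, bin_ms = 1, smoothing_ms = 10, epoch_ms = c(0, 180))
  expect_equal(sum(ps$rate_hz), sum(p$rate_hz), tolerance = 1e-9)
  expect_error(compute_psth(list()), "non-empty")
})

test_that("modulation statistic matches direct computation", {
  sl <- list(c(5, 15, 15.5), c(25), numeric(0))
  res <- temporal_modulation_test(sl, epoch_ms = c(0, 30), bin_ms = 10,
                                  n_perm = 10, seed = 1)
  rates <- c(1, 2, 1) / (3 * 10 / 1000)
  expect_equal(res$statistic, sum((rates - mean(rates))^2))
  expect_equal(res$n_spikes, 4L)
  expect_error(temporal_modulation_test(sl, n_perm = 0), "n_perm")
  expect_equal(temporal_modulation_test(list(numeric(0)))$p_value, 1)
})

test_that("permutation p-values are valid and near-uniform under the null", {
  set.seed(301)
  n_units <- 200
  pvals <- vapply(seq_len(n_units), function(u) {
    sl <- lapply(1:100, function(i) sort(stats::runif(stats::rpois(1, 1.8),
                                                      0, 180)))
    temporal_modulation_test(sl, n_perm = 200, seed = 1000 + u)$p_value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / n_units)
  expect_lte(rej, 0.05 + 3 * se)
  # chi-square goodness of fit to uniformity over deciles (p-values lie on
  # the permutation grid, so a KS test would see ties)
  counts <- table(cut(pvals, seq(0, 1, 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("the permutation test has power against a transient response", {
  set.seed(302)
  # 5-Hz baseline plus a reliable 50-Hz transient at 20-30 ms, 100 trials
  sl <- lapply(1:100, function(i) {
    base <- stats::runif(stats::rpois(1, 5 * 0.18), 0, 180)
    burst <- stats::runif(stats::rpois(1, 50 * 0.010), 20, 30)
    sort(c(base, burst))
  })
  res <- temporal_modulation_test(sl, n_perm = 2000, seed = 7)
  expect_lt(res$p_value, 0.001)
})

test_that("evoked-response metrics locate constructed transients", {
  # flat (empty) response
  flat <- replicate(20, numeric(0), simplify = FALSE)
  ev0 <- evoked_response(flat, pulse_onset_ms = 50)
  expect_equal(ev0$peak_modulation_hz, 0)
  expect_equal(ev0$mean_evoked_hz, 0)
  expect_false(ev0$significant)
  # transient peaking 12 ms after onset in every trial
  set.seed(303)
  sl <- lapply(1:200, function(i)
    sort(stats::runif(stats::rpois(1, 3), 11.2, 13.2) + 50))
  ev <- evoked_response(sl, pulse_onset_ms = 50)
  expect_lt(abs(ev$peak_latency_ms - 12), 2)
  expect_gt(ev$peak_modulation_hz, 20)
  expect_true(ev$significant)
  expect_gt(ev$mean_evoked_hz, 0)
  # windows outside the epoch are rejected
  expect_error(evoked_response(sl, pulse_onset_ms = 240), "epoch")
  expect_error(evoked_response(sl, pulse_onset_ms = -20), "epoch")
})

test_that("adaptation ratios follow the printed arithmetic", {
  expect_equal(adaptation_ratio(c(10, 10, 10)), c(1, 1))
  expect_equal(adaptation_ratio(c(20, 16, 14)), c(0.80, 0.70))
  expect_true(all(is.na(adaptation_ratio(c(0, 5, 5)))))
  expect_error(adaptation_ratio(5), "two pulses")
  m <- rbind(c(0.8, 0.7), c(0.9, 0.6), c(NA, NA))
  s <- adaptation_summary(m)
  expect_equal(s$mean, c(0.85, 0.65))
  expect_equal(s$n, c(2, 2))
})

test_that("imposed per-pulse adaptation is recovered from simulated units", {
  imposed <- c(1, 0.8, 0.7)
  onsets <- pulse_onsets(lib4$FFF)
  n_units <- 50
  trials <- data.frame(trial_id = 1:200, stimulus = "FFF", choice = "left",
                       correct = FALSE, withdrawal_ms = 190)
  ratios <- t(vapply(seq_len(n_units), function(u) {
    arch <- unit_archetype("Fast", adaptation_ratios = imposed)
    sp <- simulate_unit(arch, trials, lib4, seed = 400 + u)
    sl <- split(sp$time_ms, factor(sp$trial_id, levels = trials$trial_id))
    ev <- vapply(onsets, function(o)
      evoked_response(sl, o)$mean_evoked_hz, numeric(1))
    adaptation_ratio(ev)
  }, numeric(2)))
  s <- adaptation_summary(ratios)
  expect_lt(abs(s$mean[1] - 0.8), 2 * s$sem[1])
  expect_lt(abs(s$mean[2] - 0.7), 2 * s$sem[2])
})

test_that("choice bias is antisymmetric and detects imposed choice gain", {
  cfg <- session_config(n_trials_per_stimulus = 40,
                        units = c(SlowPos = 6, Fast = 2), seed = 21)
  s <- generate_session(cfg)
  final_onsets <- vapply(s$stimuli, function(x) max(pulse_onsets(x)),
                         numeric(1))
  sl <- unit_spike_list(s, "u001")
  cb <- choice_bias(sl, s$trials, final_onsets)
  # swapping choice labels negates the bias exactly
  flipped <- s$trials
  flipped$choice <- ifelse(s$trials$choice == "right", "left", "right")
  cb2 <- choice_bias(sl, flipped, final_onsets)
  expect_equal(cb$bias_hz, -cb2$bias_hz)
  # SlowPos population: positive bias, significant; baseline comparison not
  pop <- population_choice_bias(s,
                                unit_ids = s$units$unit_id[s$units$true_class == "SlowPos"])
  expect_gt(pop$mean_bias_hz, 0)
  expect_lt(pop$p_value, 0.05)
  # a single-choice trial subset yields NA bias
  right_only <- s$trials[s$trials$choice == "right", ]
  sl_r <- unit_spike_list(s, "u001", right_only)
  expect_true(is.na(choice_bias(sl_r, right_only, final_onsets)$bias_hz))
})

test_that("choice-blind populations rarely show significant bias", {
  runs <- 30
  sig <- vapply(seq_len(runs), function(r) {
    cfg <- session_config(n_trials_per_stimulus = 15,
                          units = c(Unmodulated = 10), seed = 500 + r)
    s <- generate_session(cfg)
    population_choice_bias(s)$p_value < 0.05
  }, logical(1))
  # expect ~5% false positives; allow up to 4/30
  expect_lte(sum(sig), 4)
})

test_that("divergence time finds the onset of a sustained choice difference", {
  edges <- 0:180
  n_units <- 20
  set.seed(304)
  right <- matrix(stats::rnorm(n_units * 180, 10, 1), n_units)
  left <- right
  post <- which(edges[-length(edges)] >= 120)
  left[, post] <- matrix(stats::rnorm(n_units * length(post), 7, 1), n_units)
  # identical traces: no divergence
  none <- divergence_time(right, right, edges)
  expect_true(is.na(none$divergence_ms))
  dv <- divergence_time(right, left, edges)
  expect_false(is.na(dv$divergence_ms))
  expect_lte(abs(dv$divergence_ms - 120), 10)
  # persistence 1 reduces to the first significant window
  dv1 <- divergence_time(right, left, edges, persist = 1)
  expect_equal(dv1$divergence_ms,
               dv1$window_start_ms[which(dv1$p_values < 0.05)[1]])
})
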