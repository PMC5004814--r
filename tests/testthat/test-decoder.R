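# Population decoding of stimulus identity and behavioral choice.

make_poisson_session <- function(n_units, n_trials_per_stim, seed = 1) {
  stationary_poisson_session(n_units, n_trials_per_stim, rate_hz = 10,
                             seed = seed)
}

test_that("spike trains are binned per specification", {
  expect_equal(bin_spike_train(numeric(0), bin_spec(10)), rep(0L, 15))
  v <- bin_spike_train(12, bin_spec(10))
  expect_equal(which(v == 1), 2)
  expect_length(v, 15)
  expect_equal(bin_spike_train(c(3, 40, 149.9, 150, 200), bin_spec(NULL)), 3)
  # last 100 ms before withdrawal
  pw <- bin_spec(pre_withdrawal_ms = 100)
  expect_equal(bin_spike_train(c(50, 95, 180), pw, withdrawal_ms = 190), 2)
  expect_error(bin_spike_train(1, pw), "withdrawal")
})

test_that("rate normalization and time scrambling behave as controls", {
  expect_equal(rate_normalize(c(3, 4)), c(0.6, 0.8))
  expect_equal(rate_normalize(numeric(5)), numeric(5))
  m <- rate_normalize(rbind(c(3, 4), c(0, 0)))
  expect_equal(m[1, ], c(0.6, 0.8))
  s <- make_poisson_session(3, 10, seed = 2)
  sc <- time_scramble_session(s, seed = 9)
  key <- function(x) table(paste(x$unit_id, x$trial_id))
  expect_equal(key(sc$spikes), key(s$spikes))  # per-trial counts preserved
  inside <- sc$spikes$time_ms >= 0 & sc$spikes$time_ms < 150
  expect_true(any(sc$spikes$time_ms[inside] !=
                    s$spikes$time_ms[s$spikes$time_ms >= 0 &
                                       s$spikes$time_ms < 150]))
  expect_identical(time_scramble_session(s, seed = 9), sc)
})

test_that("penalized logistic fit agrees with glm at negligible penalty", {
  set.seed(501)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, plogis(0.5 + X %*% c(1, -0.5, 0.2)))
  b <- vibrotact:::.ridge_logistic(X, y, lambda = 1e-10)
  ref <- coef(glm(y ~ X, family = binomial))
  expect_equal(unname(b), unname(ref), tolerance = 1e-5)
  # single-lambda CV path reduces to the plain fit
  b2 <- vibrotact:::.cv_ridge_logistic(X, y, lambdas = 1e-10)
  expect_equal(b2, b)
  # penalty shrinks slopes toward zero but not the intercept
  bp <- vibrotact:::.ridge_logistic(X, y, lambda = 100)
  expect_lt(sum(abs(bp[-1])), sum(abs(b[-1])))
})

test_that("one-vs-all unit decoders separate separable classes", {
  labels <- rep(c("A", "B", "C", "D"), each = 20)
  counts <- matrix(0, 80, 4)
  counts[cbind(seq_len(80), rep(1:4, each = 20))] <- 5  # one hot, separable
  d <- fit_unit_ova(counts, labels, seed = 3)
  p <- predict_unit(d, counts[d$train, , drop = FALSE])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  pred <- d$classes[max.col(p)]
  expect_equal(mean(pred == labels[d$train]), 1)
  # determinism given seed
  d2 <- fit_unit_ova(counts, labels, seed = 3)
  expect_identical(d$coef, d2$coef)
  expect_error(fit_unit_ova(counts, rep("A", 80)), "2 classes")
})

test_that("population prediction sums probabilities with equal unit weight", {
  mk <- function(coef) structure(list(coef = coef, classes = c("A", "B")),
                                 class = "unit_decoder")
  # unit 1 votes B weakly, unit 2 votes A strongly
  u1 <- mk(rbind(A = c(-0.2, 0), B = c(0.2, 0)))
  u2 <- mk(rbind(A = c(2, 0), B = c(-2, 0)))
  expect_equal(predict_population(list(u1), list(0)), "B")
  expect_equal(predict_population(list(u1, u2), list(0, 0)), "A")
  # hand-computed: p1 = (0.45, 0.55), p2 = (0.88, 0.12) -> A wins
  p1 <- drop(predict_unit(u1, 0)); p2 <- drop(predict_unit(u2, 0))
  expect_gt(p1[["A"]] + p2[["A"]], p1[["B"]] + p2[["B"]])
  expect_error(predict_population(list(), list()), "empty")
})

fast_session <- generate_session(
  session_config(n_trials_per_stimulus = 40, units = c(Fast = 12), seed = 5))

test_that("Fast populations decode stimulus identity well above chance", {
  rep10 <- evaluate_stimulus_decoder(fast_session, bin_spec(10),
                                     n_repeats = 10, seed = 2)
  expect_true(all(abs(rowSums(rep10$confusion) - 1) < 1e-9))
  expect_gt(rep10$overall_pct, 40)
  # FMS and SMF are identified, not merely lumped
  expect_gt(rep10$confusion["FMS", "FMS"], rep10$confusion["FMS", "SMF"])
  expect_gt(rep10$confusion["SMF", "SMF"], rep10$confusion["SMF", "FMS"])
  # single 150-ms bin loses accuracy relative to 10-ms bins
  rep1 <- evaluate_stimulus_decoder(fast_session, bin_spec(NULL),
                                    n_repeats = 10, seed = 2)
  expect_lt(rep1$overall_pct, rep10$overall_pct)
  # rate normalization preserves temporal decoding ...
  repn <- evaluate_stimulus_decoder(fast_session, bin_spec(10),
                                    n_repeats = 10, control = "rate_norm",
                                    seed = 2)
  expect_gt(repn$overall_pct, 40)
  # ... while time scrambling collapses it toward chance
  reps <- evaluate_stimulus_decoder(time_scramble_session(fast_session,
                                                          seed = 3),
                                    bin_spec(10), n_repeats = 10, seed = 2)
  expect_lt(reps$overall_pct, rep10$overall_pct - 10)
  expect_lt(reps$overall_pct, 37.5)
})

test_that("stimulus-independent units decode at chance (25%)", {
  # average over independent sessions: at this size the dominant Monte-Carlo
  # noise is dataset-level (finite trials), not repeat-level
  reps <- lapply(1:3, function(k) {
    s <- make_poisson_session(20, 30, seed = 5 + k)
    evaluate_stimulus_decoder(s, bin_spec(10), n_repeats = 12, seed = 4 + k)
  })
  acc <- vapply(reps, `[[`, numeric(1), "overall_pct")
  expect_lt(abs(mean(acc) - 25), 5)
  # per-unit accuracies also hover at chance
  pu <- unlist(lapply(reps, `[[`, "per_unit_pct"))
  expect_lt(abs(mean(pu) - 25), 4)
})

test_that("Slow populations carry little stimulus information", {
  s <- generate_session(session_config(n_trials_per_stimulus = 40,
                                       units = c(SlowPos = 6, SlowNeg = 6),
                                       seed = 7))
  rep <- evaluate_stimulus_decoder(s, bin_spec(10), n_repeats = 10, seed = 4)
  expect_lt(rep$overall_pct, 40)
})

test_that("choice decoding separates Slow from Fast populations", {
  cfg <- session_config(n_trials_per_stimulus = 40,
                        units = c(SlowPos = 8), seed = 8)
  slow <- generate_session(cfg)
  repc <- evaluate_choice_decoder(slow, bin_spec(NULL), n_repeats = 15,
                                  seed = 5)
  expect_true(all(repc$per_stimulus_pct > 50, na.rm = TRUE))
  # pre-withdrawal window also carries the choice signal
  repw <- evaluate_choice_decoder(slow, bin_spec(pre_withdrawal_ms = 100),
                                  n_repeats = 15, seed = 5)
  expect_gt(repw$mean_pct, 50)
  # Fast units without choice gain cannot predict choice
  fast_rep <- evaluate_choice_decoder(fast_session, bin_spec(NULL),
                                      n_repeats = 15, seed = 5)
  expect_lt(fast_rep$mean_pct, 60)
})

test_that("choice-blind units decode choice at chance (50%)", {
  # averaged over independent sessions (dataset-level noise dominates at
  # this size, as for the stimulus decoder above)
  acc <- vapply(1:5, function(k) {
    s <- make_poisson_session(30, 50, seed = 8 + k)
    evaluate_choice_decoder(s, bin_spec(NULL), n_repeats = 12,
                            seed = 5 + k)$mean_pct
  }, numeric(1))
  expect_lt(abs(mean(acc) - 50), 5)
})

test_that("uninformative units do not change expected accuracy appreciably", {
  base <- evaluate_stimulus_decoder(fast_session, bin_spec(10),
                                    n_repeats = 8, seed = 11)
  extra <- generate_session(session_config(n_trials_per_stimulus = 40,
                                           units = c(Fast = 12,
                                                     Unmodulated = 6),
                                           seed = 5))
  aug <- evaluate_stimulus_decoder(extra, bin_spec(10), n_repeats = 8,
                                   seed = 11)
  expect_lt(abs(aug$overall_pct - base$overall_pct), 10)
})
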