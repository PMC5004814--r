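# Pulse/sequence construction and speed features.

lib <- sequence_library()

test_that("pulse construction reproduces the printed kinematic arithmetic", {
  fast <- lib$FFF$pulses[[1]]
  expect_equal(fast$duration_ms, 16)
  w <- build_pulse(fast, dt_ms = 0.5)
  tt <- waveform_times(w)
  expect_equal(range(tt), c(0, 16))
  # starts and ends at rest
  expect_equal(w$position_mm[1], 0, tolerance = 1e-9)
  expect_equal(w$position_mm[length(w$position_mm)], 0, tolerance = 1e-9)
  expect_equal(max(w$position_mm), fast$amplitude_mm)
  # closed-form peak speed of the raised-cosine ramp: 1000*A*pi/(2*T_rise)
  expect_equal(max(abs(w$velocity_mm_s)), 1000 * 1.03 * pi / 16,
               tolerance = 1e-12)
  expect_equal(pulse_peak_velocity(fast), 1000 * 1.03 * pi / 16)
  # velocity matches numerical differentiation of position
  num <- diff(w$position_mm) / 0.5 * 1000
  mid <- (w$velocity_mm_s[-1] + w$velocity_mm_s[-length(w$velocity_mm_s)]) / 2
  expect_lt(max(abs(num - mid)), 0.01 * max(abs(w$velocity_mm_s)))
})

test_that("invalid pulse parameters and non-divisible sampling are rejected", {
  expect_error(pulse_spec("F", 8, 8, 0), "amplitude")
  expect_error(build_pulse(lib$FFF$pulses[[1]], dt_ms = 3), "divide")
  # tiny amplitude scales linearly and still returns to zero
  eps <- 1e-6
  w <- build_pulse(pulse_spec("F", 8, 8, eps), dt_ms = 0.5)
  expect_equal(max(w$position_mm), eps)
  expect_equal(w$position_mm[length(w$position_mm)], 0, tolerance = 1e-15)
})

test_that("sequence timing matches the printed intervals and durations", {
  expect_equal(sequence_duration(lib$FSFS), 188)   # 4 pulses, 34-ms gaps
  expect_equal(sequence_duration(lib$SFFS), 188)
  expect_equal(diff(pulse_onsets(lib$SSS))[1], 62) # S duration 28 + 34
  expect_equal(diff(pulse_onsets(lib$FFF))[1], 50) # F duration 16 + 34
  # single-pulse sequence duration equals the pulse duration
  solo <- sequence_spec("solo", lib$FFF$pulses[1], gap_ms = 34)
  expect_equal(sequence_duration(solo), 16)
  w <- build_sequence(lib$FFF, 0.5)
  expect_equal(max(waveform_times(w)), sequence_duration(lib$FFF))
  # gap regions are motionless
  tt <- waveform_times(w)
  gap <- tt > 16 & tt < 50
  expect_true(all(w$position_mm[gap] == 0))
})

test_that("total travel of any pulse equals twice its amplitude", {
  for (nm in c("F", "M", "S")) {
    p <- switch(nm, F = lib$FFF$pulses[[1]], M = lib$FMS$pulses[[2]],
                S = lib$SSS$pulses[[1]])
    w <- build_pulse(p, dt_ms = 0.1)
    expect_equal(total_travel(w), 2 * p$amplitude_mm,
                 tolerance = 1e-3)
  }
})

test_that("mean speed behaves as a time-average of |velocity|", {
  # zero waveform
  z <- waveform(0, 1, rep(0, 201), rep(0, 201))
  expect_equal(mean_speed(z, c(0, 150)), 0)
  # triangular ramp-return pulse: amplitude A over duration T -> 2A/T mm/ms
  A <- 1.2; T <- 20
  tt <- seq(0, T, 0.5)
  pos <- A * (1 - abs(2 * tt / T - 1))
  vel <- 1000 * ifelse(tt <= T / 2, 2 * A / T, -2 * A / T)
  tri <- waveform(0, 0.5, pos, vel)
  expect_equal(mean_speed(tri, c(0, T)), 2000 * A / T, tolerance = 1e-9)
  # FMS and SMF share pulse sets: equal mean speed over a common 150-ms window
  ms_fms <- mean_speed(build_sequence(lib$FMS, 0.5), c(0, 150))
  ms_smf <- mean_speed(build_sequence(lib$SMF, 0.5), c(0, 150))
  expect_lt(abs(ms_fms - ms_smf) / ms_fms, 0.01)
  # time reversal leaves mean speed unchanged
  w <- build_sequence(lib$FMS, 0.5)
  rev_w <- waveform(0, 0.5, rev(w$position_mm), -rev(w$velocity_mm_s))
  expect_equal(mean_speed(w, c(0, 134)), mean_speed(rev_w, c(0, 134)),
               tolerance = 1e-9)
})

test_that("own-duration mean speed orders the four sequences FFF > FMS = SMF > SSS", {
  ms <- vapply(lib[c("FFF", "FMS", "SMF", "SSS")], sequence_mean_speed,
               numeric(1))
  expect_gt(ms["FFF"], ms["FMS"])
  expect_gt(ms["SMF"], ms["SSS"])
  expect_lt(abs(ms["FMS"] - ms["SMF"]) / ms["FMS"], 0.01)
})

test_that("integrated-speed regressor matches analytic integrals", {
  # zero waveform -> all-zero regressor
  z <- waveform(0, 1, rep(0, 301), rep(0, 301))
  expect_equal(integrated_speed_regressor(z, 60), rep(0, 36))
  # constant speed c: regressor = c * W / 1000 mm once the window is filled
  cc <- 80
  const <- waveform(-200, 1, seq(0, 0.4, length.out = 601),
                    rep(cc, 601))
  for (W in c(5, 50, 180))
    expect_equal(integrated_speed_regressor(const, W),
                 rep(cc * W / 1000, 36), tolerance = 1e-9)
  # W = 5: value for bin [5,10) is the integral of |v| over [0,5)
  w <- build_sequence(lib$FFF, 0.5)
  r5 <- integrated_speed_regressor(w, 5)
  tt <- waveform_times(w); s <- abs(w$velocity_mm_s) / 1000
  keep <- tt <= 5
  direct <- sum((s[keep][-1] + s[keep][-sum(keep)]) / 2 * 0.5)
  expect_equal(r5[2], direct, tolerance = 1e-9)
  # off-grid window rejected
  expect_error(integrated_speed_regressor(w, 7), "grid")
})

test_that("regressor is non-negative and non-decreasing in W", {
  w <- build_sequence(lib$SMF, 0.5)
  grid <- seq(5, 180, 5)
  regs <- sapply(grid, function(W) integrated_speed_regressor(w, W))
  expect_true(all(regs >= 0))
  expect_true(all(diff(t(regs)) >= -1e-12))  # across W for each bin
})

test_that("waveform CSV export round-trips", {
  w <- build_pulse(lib$FFF$pulses[[1]], 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  back <- utils::read.csv(path)
  expect_equal(back$position_mm, w$position_mm)
  expect_equal(back$time_ms, waveform_times(w))
})
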