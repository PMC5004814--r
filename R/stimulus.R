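# Stimulus kinematics: parametric whisker-panel pulses, pulse sequences,
# sampled waveforms, and the integrated-speed regressors used by the
# integration-window analysis.
#
# Units convention (package-wide): time in ms, position in mm, velocity and
# speed in mm/s, rate in Hz.

#' Describe a single whisker panel impulse
#'
#' A pulse is an up-down ramp-return deflection of the stimulus panel with a
#' raised-cosine position profile: the panel rises smoothly to
#' `amplitude_mm` over `rise_ms` and returns to rest over `fall_ms`, so the
#' peak velocity occurs mid-ramp. Fast (F), Medium (M) and Slow (S) impulses
#' differ in rise/fall time (8, 11, 14 ms) and hence duration, at similar
#' amplitude.
#'
#' @param label Single character label, conventionally `"F"`, `"M"` or `"S"`.
#' @param rise_ms Rise time in ms (> 0).
#' @param fall_ms Fall time in ms (> 0).
#' @param amplitude_mm Peak panel displacement in mm (> 0).
#' @param nominal_peak_velocity_mm_s Optional informational peak velocity in
#'   mm/s as specified for the actuator; the analytic peak velocity of the
#'   raised-cosine profile is available via [pulse_peak_velocity()].
#' @return An object of class `pulse_spec` with a derived `duration_ms =
#'   rise_ms + fall_ms`.
#' @seealso [build_pulse()], [sequence_spec()]
#' @export
pulse_spec <- function(label, rise_ms, fall_ms, amplitude_mm,
                       nominal_peak_velocity_mm_s = NA_real_) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(rise_ms) || length(rise_ms) != 1L || rise_ms <= 0)
    stop("rise_ms must be a single positive number")
  if (!is.numeric(fall_ms) || length(fall_ms) != 1L || fall_ms <= 0)
    stop("fall_ms must be a single positive number")
  if (!is.numeric(amplitude_mm) || length(amplitude_mm) != 1L || amplitude_mm <= 0)
    stop("amplitude_mm must be a single positive number")
  structure(
    list(label = label, rise_ms = as.numeric(rise_ms),
         fall_ms = as.numeric(fall_ms), amplitude_mm = as.numeric(amplitude_mm),
         nominal_peak_velocity_mm_s = as.numeric(nominal_peak_velocity_mm_s),
         duration_ms = as.numeric(rise_ms + fall_ms)),
    class = "pulse_spec")
}

#' Analytic peak speed of a raised-cosine pulse
#'
#' For a raised-cosine ramp of amplitude A (mm) over T (ms) the peak speed is
#' `1000 * A * pi / (2 * T)` mm/s, reached mid-ramp. The value returned is the
#' maximum over the rise and fall ramps.
#'
#' @param spec A [pulse_spec()].
#' @return Peak |velocity| in mm/s.
#' @export
pulse_peak_velocity <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  1000 * spec$amplitude_mm * pi / 2 * max(1 / spec$rise_ms, 1 / spec$fall_ms)
}

#' Describe a whisker impulse sequence
#'
#' A sequence is an ordered train of pulses separated by a fixed quiet gap
#' (interpulse interval, measured end-of-pulse to start-of-next). The
#' four-stimulus discrimination set uses three-pulse trains (FFF, FMS, SMF,
#' SSS) with a 34-ms gap, giving 50-62 ms between pulse onsets.
#'
#' @param name Sequence name (e.g. `"FFF"`).
#' @param pulses List of [pulse_spec()] objects, in presentation order.
#' @param gap_ms Interpulse interval in ms (>= 0), end-to-start.
#' @param reward_side `"left"` or `"right"`: the rewarded drink port.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(name, pulses, gap_ms = 34, reward_side = c("right", "left")) {
  reward_side <- match.arg(reward_side)
  if (!is.list(pulses) || length(pulses) < 1L ||
      !all(vapply(pulses, inherits, logical(1), "pulse_spec")))
    stop("pulses must be a non-empty list of pulse_spec objects")
  if (!is.numeric(gap_ms) || length(gap_ms) != 1L || gap_ms < 0)
    stop("gap_ms must be a single non-negative number")
  structure(
    list(name = name, pulses = pulses, gap_ms = as.numeric(gap_ms),
         reward_side = reward_side),
    class = "sequence_spec")
}

#' Pulse onset times of a sequence
#'
#' @param spec A [sequence_spec()].
#' @return Numeric vector of pulse onset times in ms relative to sequence
#'   onset; consecutive onsets are separated by the preceding pulse duration
#'   plus the gap.
#' @export
pulse_onsets <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  durs <- unname(vapply(spec$pulses, function(p) p$duration_ms, numeric(1)))
  n <- length(durs)
  c(0, cumsum(durs[-n] + spec$gap_ms))[seq_len(n)]
}

#' Total duration of a sequence
#'
#' @param spec A [sequence_spec()].
#' @return Duration in ms from first pulse onset to last pulse offset:
#'   the sum of pulse durations plus `(n - 1) * gap_ms`.
#' @export
sequence_duration <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  durs <- vapply(spec$pulses, function(p) p$duration_ms, numeric(1))
  sum(durs) + (length(durs) - 1) * spec$gap_ms
}

## internal: raised-cosine position (mm) and velocity (mm/s) of one pulse at
## times t (ms) relative to the pulse onset; zero outside [0, duration].
.pulse_position <- function(t, spec) {
  A <- spec$amplitude_mm; Tr <- spec$rise_ms; Tf <- spec$fall_ms
  pos <- numeric(length(t))
  r <- t >= 0 & t <= Tr
  pos[r] <- A / 2 * (1 - cos(pi * t[r] / Tr))
  f <- t > Tr & t <= Tr + Tf
  pos[f] <- A / 2 * (1 + cos(pi * (t[f] - Tr) / Tf))
  pos
}

.pulse_velocity <- function(t, spec) {
  A <- spec$amplitude_mm; Tr <- spec$rise_ms; Tf <- spec$fall_ms
  vel <- numeric(length(t))
  r <- t >= 0 & t <= Tr
  vel[r] <- 1000 * A * pi / (2 * Tr) * sin(pi * t[r] / Tr)
  f <- t > Tr & t <= Tr + Tf
  vel[f] <- -1000 * A * pi / (2 * Tf) * sin(pi * (t[f] - Tr) / Tf)
  vel
}

.new_waveform <- function(t0_ms, dt_ms, position_mm, velocity_mm_s) {
  stopifnot(length(position_mm) == length(velocity_mm_s))
  structure(
    list(dt_ms = dt_ms, t0_ms = t0_ms,
         position_mm = position_mm, velocity_mm_s = velocity_mm_s),
    class = "waveform")
}

#' Time axis of a waveform
#' @param w A `waveform`.
#' @return Sample times in ms.
#' @export
waveform_times <- function(w) {
  stopifnot(inherits(w, "waveform"))
  w$t0_ms + (seq_along(w$position_mm) - 1) * w$dt_ms
}

#' Construct a waveform from explicit samples
#'
#' Mainly for constructing test waveforms with known analytic properties
#' (velocity may be supplied directly; otherwise it is computed by central
#' differences of position).
#'
#' @param t0_ms Time of the first sample (ms).
#' @param dt_ms Sample step (ms).
#' @param position_mm Position samples (mm).
#' @param velocity_mm_s Optional velocity samples (mm/s).
#' @return A `waveform`.
#' @export
waveform <- function(t0_ms, dt_ms, position_mm, velocity_mm_s = NULL) {
  if (is.null(velocity_mm_s)) {
    n <- length(position_mm)
    velocity_mm_s <- 1000 * c(position_mm[2] - position_mm[1],
                              (position_mm[-(1:2)] - position_mm[1:(n - 2)]) / 2,
                              position_mm[n] - position_mm[n - 1]) / dt_ms
  }
  .new_waveform(t0_ms, dt_ms, position_mm, velocity_mm_s)
}

.check_divisible <- function(dt_ms, interval_ms, what) {
  k <- interval_ms / dt_ms
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("dt_ms = %g does not divide %s = %g ms", dt_ms, what, interval_ms))
}

#' Sample a single pulse waveform
#'
#' Raised-cosine up-ramp to `amplitude_mm` over `rise_ms`, raised-cosine
#' return to zero over `fall_ms`. Velocity is the analytic derivative of the
#' position profile.
#'
#' @param spec A [pulse_spec()].
#' @param dt_ms Sample step in ms; must divide both rise and fall times.
#' @return A `waveform` sampled on `[0, duration_ms]` (inclusive endpoints).
#' @export
build_pulse <- function(spec, dt_ms = 0.5) {
  stopifnot(inherits(spec, "pulse_spec"))
  .check_divisible(dt_ms, spec$rise_ms, "rise_ms")
  .check_divisible(dt_ms, spec$fall_ms, "fall_ms")
  t <- seq(0, spec$duration_ms, by = dt_ms)
  .new_waveform(0, dt_ms, .pulse_position(t, spec), .pulse_velocity(t, spec))
}

#' Sample a full sequence waveform
#'
#' Pulses are concatenated with `gap_ms` of zero motion between the offset of
#' one pulse and the onset of the next. Total support runs from the first
#' pulse onset (t = 0) to the last pulse offset.
#'
#' @param spec A [sequence_spec()].
#' @param dt_ms Sample step in ms; must divide every rise/fall time, the gap,
#'   and hence every pulse onset.
#' @return A `waveform` over `[0, sequence_duration(spec)]`.
#' @export
build_sequence <- function(spec, dt_ms = 0.5) {
  stopifnot(inherits(spec, "sequence_spec"))
  for (p in spec$pulses) {
    .check_divisible(dt_ms, p$rise_ms, "rise_ms")
    .check_divisible(dt_ms, p$fall_ms, "fall_ms")
  }
  if (spec$gap_ms > 0) .check_divisible(dt_ms, spec$gap_ms, "gap_ms")
  onsets <- pulse_onsets(spec)
  total <- sequence_duration(spec)
  t <- seq(0, total, by = dt_ms)
  pos <- numeric(length(t)); vel <- numeric(length(t))
  for (k in seq_along(spec$pulses)) {
    tk <- t - onsets[k]
    pos <- pos + .pulse_position(tk, spec$pulses[[k]])
    vel <- vel + .pulse_velocity(tk, spec$pulses[[k]])
  }
  .new_waveform(0, dt_ms, pos, vel)
}

## internal: speed (|velocity|, mm/s) of w at arbitrary times (ms), linearly
## interpolated, zero outside the sampled support.
.speed_at <- function(w, t) {
  tt <- waveform_times(w)
  stats::approx(tt, abs(w$velocity_mm_s), xout = t, yleft = 0, yright = 0)$y
}

#' Mean panel speed over a time window
#'
#' Time-average of |velocity| over `window_ms`, zero-padding outside the
#' waveform's sampled support. This is the integrated ("intensity") stimulus
#' feature that behavioral choice tracks.
#'
#' @param w A `waveform`.
#' @param window_ms Length-2 numeric `c(start, end)` in ms, end > start.
#' @return Mean speed in mm/s.
#' @export
mean_speed <- function(w, window_ms) {
  stopifnot(inherits(w, "waveform"))
  if (length(window_ms) != 2L || !is.numeric(window_ms) ||
      diff(window_ms) <= 0)
    stop("window_ms must be c(start, end) with end > start")
  grid <- seq(window_ms[1], window_ms[2], by = w$dt_ms)
  if (grid[length(grid)] < window_ms[2]) grid <- c(grid, window_ms[2])
  s <- .speed_at(w, grid)
  trap <- sum((s[-1] + s[-length(s)]) / 2 * diff(grid))
  trap / diff(window_ms)
}

#' Mean speed of a sequence over its own duration
#'
#' Convenience wrapper: mean speed from first pulse onset to last pulse
#' offset. This is the feature under which the four-stimulus set orders
#' FFF > FMS = SMF > SSS.
#'
#' @param spec A [sequence_spec()].
#' @param dt_ms Sample step for the internal waveform.
#' @return Mean speed in mm/s.
#' @export
sequence_mean_speed <- function(spec, dt_ms = 0.5) {
  w <- build_sequence(spec, dt_ms)
  mean_speed(w, c(0, sequence_duration(spec)))
}

#' Integrated-speed regressor for the window regression
#'
#' For each 5-ms firing-rate bin `[t, t + bin_ms)` of the 0-180 ms analysis
#' epoch, the regressor value is the integral of panel speed over the
#' preceding window `[t - W, t)` (mm of integrated travel), zero-padding
#' speed before sequence onset. Speed in the immediately preceding window
#' predicts rate in the subsequent bin.
#'
#' @param w A `waveform` (sequence onset at t = 0).
#' @param window_W_ms Integration window W in ms; must lie on the 5-ms grid
#'   5, 10, ..., 180.
#' @param bin_ms Rate bin width in ms (default 5).
#' @param epoch_ms Analysis epoch, default `c(0, 180)`.
#' @return Numeric vector with one value per rate bin (36 by default), in mm.
#' @export
integrated_speed_regressor <- function(w, window_W_ms, bin_ms = 5,
                                       epoch_ms = c(0, 180)) {
  stopifnot(inherits(w, "waveform"))
  if (!is.numeric(window_W_ms) || length(window_W_ms) != 1L ||
      window_W_ms < bin_ms || window_W_ms > 180 ||
      abs(window_W_ms / 5 - round(window_W_ms / 5)) > 1e-9)
    stop("window_W_ms must be on the 5-ms grid 5, 10, ..., 180")
  starts <- seq(epoch_ms[1], epoch_ms[2] - bin_ms, by = bin_ms)
  cumint <- .cumulative_travel(w)
  cumint(starts) - cumint(starts - window_W_ms)
}

## internal: returns a function C(t) = integral of |velocity| (mm) from
## -Inf to t, computed by trapezoid over the waveform samples, zero before
## the first sample and constant after the last.
.cumulative_travel <- function(w) {
  tt <- waveform_times(w)
  s <- abs(w$velocity_mm_s) / 1000      # mm per ms
  ct <- c(0, cumsum((s[-1] + s[-length(s)]) / 2 * diff(tt)))
  function(t) stats::approx(tt, ct, xout = t, yleft = 0,
                            yright = ct[length(ct)])$y
}

#' Total travel of a waveform
#'
#' Integral of |velocity| over the full support; equals twice the summed
#' pulse amplitudes for ramp-return pulses.
#'
#' @param w A `waveform`.
#' @return Travel in mm.
#' @export
total_travel <- function(w) {
  .cumulative_travel(w)(max(waveform_times(w)))
}

#' Load the shipped stimulus library
#'
#' Reads the packaged YAML description of the printed pulse kinematics and
#' builds the standard sequence sets: the three-pulse FFF/FMS/SMF/SSS set and
#' the four-pulse FSFS/SFFS (same-intensity) set.
#'
#' @param path Optional path to an alternative YAML library.
#' @return Named list of [sequence_spec()] objects.
#' @export
sequence_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sequences.yaml", package = "vibrotact",
                        mustWork = TRUE)
  lib <- yaml::read_yaml(path)
  pulses <- lapply(lib$pulses, function(p)
    pulse_spec(p$label, p$rise_ms, p$fall_ms, p$amplitude_mm,
               p$nominal_peak_velocity_mm_s))
  out <- lapply(lib$sequences, function(sq)
    sequence_spec(sq$name, pulses[sq$pulses], gap_ms = sq$gap_ms,
                  reward_side = sq$reward_side))
  names(out) <- vapply(lib$sequences, `[[`, character(1), "name")
  out
}

#' Export a waveform as a two-column CSV
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  utils::write.csv(
    data.frame(time_ms = waveform_times(w), position_mm = w$position_mm),
    path, row.names = FALSE)
  invisible(path)
}
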