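# Synthetic session generator: behavioral trial tables plus inhomogeneous
# Poisson spike trains from parameterized unit archetypes, with ground-truth
# labels. Emulates the statistical structure the downstream analyses assume:
# Fast units with velocity-scaled phasic impulse responses, Medium units with
# impulse-triggered suppression, Slow Positive units with weak sustained
# impulse responses plus a choice-correlated late ramp, Slow Negative units
# with within-trial rate decline, and Unmodulated units.

TRIAL_EPOCH_MS <- c(-25, 250)

#' Define a synthetic unit archetype
#'
#' Parameterizes the trial-aligned rate function lambda(t) of one synthetic
#' unit. Classes:
#' * `Fast`: baseline plus a transient kernel at each pulse, scaled by the
#'   pulse's peak velocity (via `velocity_gain`) and a per-pulse-position
#'   adaptation multiplier.
#' * `Medium`: baseline minus a broader pulse-triggered suppression of depth
#'   `suppression_hz`.
#' * `SlowPos`: baseline plus small sustained responses to pulses 2+ and,
#'   on right-choice trials, a ramp of height `choice_gain_hz` starting
#'   after the second pulse and reaching plateau during the third.
#' * `SlowNeg`: baseline with a linear within-trial decline of
#'   `decay_rate_hz_per_ms`.
#' * `Unmodulated`: constant baseline.
#'
#' All rates are clipped at zero.
#'
#' @param class_label One of `"Fast"`, `"Medium"`, `"SlowPos"`, `"SlowNeg"`,
#'   `"Unmodulated"`.
#' @param baseline_hz Baseline rate in Hz (>= 0).
#' @param velocity_gain Hz per (mm/s) of pulse peak velocity scaling the
#'   transient (Fast) or sustained (SlowPos) response.
#' @param kernel_latency_ms,kernel_width_ms Transient-kernel latency and
#'   width (alpha kernel, peak at latency + width after pulse onset).
#' @param adaptation_ratios Per-pulse-position response multipliers; the
#'   first must be 1. Recycled to the number of pulses.
#' @param choice_gain_hz Additive rate on right-choice trials (SlowPos).
#' @param decay_rate_hz_per_ms Within-trial linear rate decline (SlowNeg).
#' @param suppression_hz Depth of pulse-triggered suppression (Medium).
#' @param layer Laminar label for the generated metadata.
#' @param spike_class `"RS"` or `"FS"`.
#' @param sort_class `"single"` or `"multi"`.
#' @return An object of class `unit_archetype`.
#' @export
unit_archetype <- function(class_label = c("Fast", "Medium", "SlowPos",
                                           "SlowNeg", "Unmodulated"),
                           baseline_hz = NULL,
                           velocity_gain = NULL,
                           kernel_latency_ms = NULL,
                           kernel_width_ms = NULL,
                           adaptation_ratios = c(1, 0.8, 0.7),
                           choice_gain_hz = 8,
                           decay_rate_hz_per_ms = 0.05,
                           suppression_hz = 14,
                           layer = NULL,
                           spike_class = "RS",
                           sort_class = "single") {
  class_label <- match.arg(class_label)
  defaults <- switch(class_label,
    Fast        = list(baseline_hz = 6, velocity_gain = 0.25,
                       kernel_latency_ms = 5, kernel_width_ms = 4,
                       layer = "L4"),
    Medium      = list(baseline_hz = 20, velocity_gain = 0,
                       kernel_latency_ms = 12, kernel_width_ms = 15,
                       layer = "L5B"),
    SlowPos     = list(baseline_hz = 8, velocity_gain = 0.05,
                       kernel_latency_ms = 8, kernel_width_ms = 25,
                       layer = "L5B"),
    SlowNeg     = list(baseline_hz = 15, velocity_gain = 0,
                       kernel_latency_ms = 5, kernel_width_ms = 4,
                       layer = "L6"),
    Unmodulated = list(baseline_hz = 8, velocity_gain = 0,
                       kernel_latency_ms = 5, kernel_width_ms = 4,
                       layer = "L2/3"))
  pick <- function(x, d) if (is.null(x)) d else x
  baseline_hz <- pick(baseline_hz, defaults$baseline_hz)
  velocity_gain <- pick(velocity_gain, defaults$velocity_gain)
  kernel_latency_ms <- pick(kernel_latency_ms, defaults$kernel_latency_ms)
  kernel_width_ms <- pick(kernel_width_ms, defaults$kernel_width_ms)
  layer <- pick(layer, defaults$layer)
  if (baseline_hz < 0) stop("baseline_hz must be >= 0")
  if (kernel_latency_ms < 0 || kernel_width_ms <= 0)
    stop("kernel latency must be >= 0 and width > 0")
  if (abs(adaptation_ratios[1] - 1) > 1e-12)
    stop("adaptation_ratios[1] must be 1")
  structure(
    list(class_label = class_label, baseline_hz = baseline_hz,
         velocity_gain = velocity_gain,
         kernel_latency_ms = kernel_latency_ms,
         kernel_width_ms = kernel_width_ms,
         adaptation_ratios = adaptation_ratios,
         choice_gain_hz = choice_gain_hz,
         decay_rate_hz_per_ms = decay_rate_hz_per_ms,
         suppression_hz = suppression_hz,
         layer = layer, spike_class = spike_class, sort_class = sort_class),
    class = "unit_archetype")
}

#' Configure a synthetic session
#'
#' @param stimulus_set Named list of [sequence_spec()] objects; default is
#'   the FFF/FMS/SMF/SSS library set.
#' @param n_trials_per_stimulus Trials per stimulus (default 50, matching
#'   typical per-session counts of 44-50).
#' @param units List of [unit_archetype()] objects (one per unit), or a
#'   named integer vector of counts per class (e.g. `c(Fast = 9, ...)`).
#' @param psychometric List with `slope` (per mm/s), `midpoint_mm_s`,
#'   `lapse` in `[0, 0.5]`, and `right_bias` (logit units). The right-choice
#'   probability for a stimulus is a lapse-adjusted logistic of its
#'   own-duration mean speed. `midpoint_mm_s = NULL` uses the midpoint of
#'   the fastest and slowest sequence speeds.
#' @param withdrawal List with `min_ms`, `mean_ms`, `shape`: nose-poke
#'   withdrawal times are `min_ms` plus a gamma with the given shape and
#'   mean `mean_ms - min_ms` (right-skewed, truncated at the task minimum).
#' @param seed Integer seed controlling the whole session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(stimulus_set = NULL,
                           n_trials_per_stimulus = 50,
                           units = c(Fast = 9, Medium = 3, SlowPos = 3,
                                     SlowNeg = 3, Unmodulated = 10),
                           psychometric = list(slope = 0.45,
                                               midpoint_mm_s = NULL,
                                               lapse = 0.05,
                                               right_bias = 0),
                           withdrawal = list(min_ms = 150, mean_ms = 190,
                                             shape = 2),
                           seed = 1L) {
  if (is.null(stimulus_set))
    stimulus_set <- sequence_library()[c("FFF", "FMS", "SMF", "SSS")]
  if (!is.list(stimulus_set) || is.null(names(stimulus_set)))
    stop("stimulus_set must be a named list of sequence_spec objects")
  if (n_trials_per_stimulus < 1) stop("n_trials_per_stimulus must be >= 1")
  if (is.numeric(units)) {
    if (any(units < 0) || sum(units) < 1)
      stop("unit counts must be non-negative with at least one unit")
    units <- unlist(lapply(names(units), function(cl)
      replicate(units[[cl]], unit_archetype(cl), simplify = FALSE)),
      recursive = FALSE)
  }
  if (!all(vapply(units, inherits, logical(1), "unit_archetype")))
    stop("units must be unit_archetype objects or a count vector")
  if (psychometric$lapse < 0 || psychometric$lapse > 0.5)
    stop("lapse must lie in [0, 0.5]")
  structure(
    list(stimulus_set = stimulus_set,
         n_trials_per_stimulus = as.integer(n_trials_per_stimulus),
         units = units, psychometric = psychometric,
         withdrawal = withdrawal, seed = as.integer(seed)),
    class = "session_config")
}

#' Simulate the behavioral trial table
#'
#' Each stimulus is presented `n_trials_per_stimulus` times in random order.
#' P(right | stimulus) is a lapse-adjusted logistic of the stimulus'
#' own-duration mean speed, so choice tracks the integrated intensity cue;
#' withdrawal times are drawn from a shifted gamma truncated at the task
#' minimum.
#'
#' @param cfg A [session_config()].
#' @param seed Optional seed (defaults to the config's seed).
#' @return Data frame with columns `trial_id`, `stimulus`, `choice`
#'   (`"right"`/`"left"`), `correct` (logical), `withdrawal_ms`.
#' @export
simulate_behavior <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "session_config"))
  speeds <- vapply(cfg$stimulus_set, sequence_mean_speed, numeric(1))
  psy <- cfg$psychometric
  mid <- psy$midpoint_mm_s
  if (is.null(mid)) mid <- (max(speeds) + min(speeds)) / 2
  p_right <- psy$lapse + (1 - 2 * psy$lapse) *
    stats::plogis(psy$slope * (speeds - mid) + psy$right_bias)
  wd <- cfg$withdrawal
  with_seed(seed, {
    stim <- sample(rep(names(cfg$stimulus_set), each = cfg$n_trials_per_stimulus))
    n <- length(stim)
    choice <- ifelse(stats::runif(n) < p_right[stim], "right", "left")
    reward <- vapply(cfg$stimulus_set, `[[`, character(1), "reward_side")
    withdrawal <- wd$min_ms +
      stats::rgamma(n, shape = wd$shape,
                    scale = (wd$mean_ms - wd$min_ms) / wd$shape)
    data.frame(trial_id = seq_len(n), stimulus = stim, choice = choice,
               correct = choice == reward[stim],
               withdrawal_ms = round(withdrawal, 1))
  })
}

## alpha kernel, peak 1 at tau = width
.alpha_kernel <- function(tau, width) {
  k <- numeric(length(tau))
  pos <- tau > 0
  k[pos] <- (tau[pos] / width) * exp(1 - tau[pos] / width)
  k
}

## sustained kernel: fast rise, slow decay, peak ~1
.sustained_kernel <- function(tau, width) {
  k <- numeric(length(tau))
  pos <- tau > 0
  k[pos] <- (1 - exp(-tau[pos] / width)) * exp(-tau[pos] / (6 * width))
  k
}

#' Trial-aligned rate function of an archetype
#'
#' Evaluates lambda(t) in Hz on a 0.1-ms grid over the trial epoch
#' (-25 to +250 ms around sequence onset) for a given stimulus and choice.
#'
#' @param arch A [unit_archetype()].
#' @param seq A [sequence_spec()].
#' @param choice `"right"` or `"left"` (only SlowPos units depend on it).
#' @param dt_ms Grid step (default 0.1 ms, the spike-time resolution).
#' @param epoch_ms Trial epoch (default -25 to 250 ms).
#' @return List with `t_ms` and `rate_hz` (clipped at zero).
#' @export
unit_rate_function <- function(arch, seq, choice = "left", dt_ms = 0.1,
                               epoch_ms = TRIAL_EPOCH_MS) {
  stopifnot(inherits(arch, "unit_archetype"), inherits(seq, "sequence_spec"))
  t <- seq(epoch_ms[1], epoch_ms[2], by = dt_ms)
  rate <- rep(arch$baseline_hz, length(t))
  onsets <- pulse_onsets(seq)
  peakv <- vapply(seq$pulses, pulse_peak_velocity, numeric(1))
  adapt <- rep_len(arch$adaptation_ratios, length(onsets))
  lat <- arch$kernel_latency_ms; wid <- arch$kernel_width_ms
  if (arch$class_label == "Fast") {
    for (k in seq_along(onsets))
      rate <- rate + arch$velocity_gain * peakv[k] * adapt[k] *
        .alpha_kernel(t - onsets[k] - lat, wid)
  } else if (arch$class_label == "Medium") {
    for (k in seq_along(onsets))
      rate <- rate - arch$suppression_hz *
        .alpha_kernel(t - onsets[k] - lat, wid)
  } else if (arch$class_label == "SlowPos") {
    if (length(onsets) >= 2) {
      for (k in 2:length(onsets))
        rate <- rate + arch$velocity_gain * peakv[k] * adapt[k] *
          .sustained_kernel(t - onsets[k] - lat, wid)
    }
    if (identical(choice, "right") && arch$choice_gain_hz != 0) {
      durs <- vapply(seq$pulses, `[[`, numeric(1), "duration_ms")
      n <- length(onsets)
      ramp_start <- if (n >= 2) onsets[2] + durs[2] else onsets[1] + durs[1]
      plateau_at <- if (n >= 3) onsets[3] + durs[3] / 2 else ramp_start + 30
      ramp <- pmin(pmax((t - ramp_start) / (plateau_at - ramp_start), 0), 1)
      rate <- rate + arch$choice_gain_hz * ramp
    }
  } else if (arch$class_label == "SlowNeg") {
    rate <- rate - arch$decay_rate_hz_per_ms * (t - epoch_ms[1])
  }
  list(t_ms = t, rate_hz = pmax(rate, 0))
}

## internal: sample one inhomogeneous Poisson spike train by thinning,
## given a rate trace (list t_ms/rate_hz). Times rounded to 0.1 ms.
.thin_spikes <- function(trace, dt_ms = 0.1) {
  lmax <- max(trace$rate_hz)
  if (lmax <= 0) return(numeric(0))
  t0 <- trace$t_ms[1]; t1 <- trace$t_ms[length(trace$t_ms)]
  n <- stats::rpois(1, lmax * (t1 - t0) / 1000)
  if (n == 0) return(numeric(0))
  cand <- stats::runif(n, t0, t1)
  idx <- pmin(pmax(round((cand - t0) / dt_ms) + 1, 1), length(trace$rate_hz))
  keep <- stats::runif(n) < trace$rate_hz[idx] / lmax
  sort(round(cand[keep], 1))
}

#' Simulate spike trains for one unit
#'
#' Independent trials; spikes drawn from an inhomogeneous Poisson process
#' with the archetype's rate function by thinning against the trace maximum.
#' Reproducible given the seed.
#'
#' @param arch A [unit_archetype()].
#' @param trials Trial table as from [simulate_behavior()].
#' @param stimulus_set Named list of [sequence_spec()] covering every
#'   stimulus in `trials`.
#' @param seed Integer seed.
#' @return Data frame with columns `trial_id`, `time_ms` (sorted within
#'   trial, 0.1-ms resolution, relative to sequence onset).
#' @export
simulate_unit <- function(arch, trials, stimulus_set, seed = 1L) {
  stopifnot(inherits(arch, "unit_archetype"), is.data.frame(trials))
  combos <- unique(trials[, c("stimulus", "choice")])
  traces <- list()
  for (i in seq_len(nrow(combos))) {
    key <- paste(combos$stimulus[i], combos$choice[i])
    traces[[key]] <- unit_rate_function(arch,
                                        stimulus_set[[combos$stimulus[i]]],
                                        combos$choice[i])
    if (!all(is.finite(traces[[key]]$rate_hz)))
      stop("rate function must be bounded")
  }
  with_seed(seed, {
    out <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      key <- paste(trials$stimulus[i], trials$choice[i])
      st <- .thin_spikes(traces[[key]])
      if (length(st))
        out[[i]] <- data.frame(trial_id = trials$trial_id[i], time_ms = st)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(trial_id = integer(0), time_ms = numeric(0))
    rownames(res) <- NULL
    res
  })
}

## layer-wise log-normal baseline medians (Hz): positively skewed rate
## distributions, lowest in L2/3, L4 and L6.
.layer_baseline_median <- c("L2/3" = 5, "L4" = 5, "L5A" = 8, "L5B" = 9,
                            "L6" = 5)

## representative depths (um) within each laminar bin for generated metadata
.layer_depth_range <- list("L2/3" = c(250, 640), "L4" = c(660, 970),
                           "L5A" = c(980, 1280), "L5B" = c(1290, 1570),
                           "L6" = c(1580, 2190))

#' Generate a complete synthetic session
#'
#' Runs [simulate_behavior()], draws per-unit baselines from layer-wise
#' log-normal distributions, simulates every unit's spike trains, and
#' assembles metadata with ground-truth archetype labels. The result has
#' the same schema as a session read from disk, plus the ground truth.
#'
#' @param cfg A [session_config()].
#' @return An object of class `session_data`: list with `trials`, `spikes`
#'   (`unit_id`, `trial_id`, `time_ms`), `units` (metadata incl.
#'   `true_class`), `stimuli`, and `config`.
#' @export
generate_session <- function(cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  n_units <- length(cfg$units)
  seeds <- child_seeds(cfg$seed, n_units + 2L)
  trials <- simulate_behavior(cfg, seed = seeds[1])
  units_meta <- vector("list", n_units)
  spikes <- vector("list", n_units)
  metadata_seed <- seeds[2]
  archs <- cfg$units
  with_seed(metadata_seed, {
    for (u in seq_len(n_units)) {
      a <- archs[[u]]
      med <- .layer_baseline_median[[a$layer]]
      if (is.null(med)) med <- 6
      # skewed baseline draw; Unmodulated units keep their archetype baseline
      # only if explicitly set, otherwise drawn like the rest
      a$baseline_hz <- stats::rlnorm(1, meanlog = log(a$baseline_hz %||% med),
                                     sdlog = 0.4)
      archs[[u]] <- a
      dr <- .layer_depth_range[[a$layer]]
      units_meta[[u]] <- data.frame(
        unit_id = sprintf("u%03d", u),
        depth_um = round(stats::runif(1, dr[1], dr[2])),
        width_ms = if (a$spike_class == "FS")
          round(stats::runif(1, 0.18, 0.34), 3) else
          round(stats::runif(1, 0.42, 0.72), 3),
        snr = round(2.2 + stats::rexp(1, 1 / 1.5), 2),
        isi_violation = round(stats::runif(1, 0, 0.004), 4),
        sort_class = a$sort_class,
        spike_class = a$spike_class,
        layer = a$layer,
        baseline_hz = round(a$baseline_hz, 2),
        true_class = a$class_label)
    }
  })
  for (u in seq_len(n_units)) {
    sp <- simulate_unit(archs[[u]], trials, cfg$stimulus_set,
                        seed = seeds[u + 2L])
    if (nrow(sp))
      spikes[[u]] <- cbind(unit_id = sprintf("u%03d", u), sp)
  }
  spikes <- do.call(rbind, spikes)
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), trial_id = integer(0),
                         time_ms = numeric(0))
  rownames(spikes) <- NULL
  out <- structure(
    list(trials = trials, spikes = spikes,
         units = do.call(rbind, units_meta),
         stimuli = cfg$stimulus_set, config = cfg),
    class = "session_data")
  validate_session(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a session from its components
#'
#' Shared constructor for synthetic and disk-read sessions; validates the
#' schema on construction.
#'
#' @param trials Trial table (`trial_id`, `stimulus`, `choice`, `correct`,
#'   `withdrawal_ms`).
#' @param spikes Spike table (`unit_id`, `trial_id`, `time_ms`).
#' @param units Unit metadata table.
#' @param stimuli Named list of [sequence_spec()] objects covering the
#'   stimuli in `trials`.
#' @param config Optional generating [session_config()].
#' @return A validated `session_data` object.
#' @export
session_data <- function(trials, spikes, units, stimuli, config = NULL) {
  out <- structure(
    list(trials = trials, spikes = spikes, units = units,
         stimuli = stimuli, config = config),
    class = "session_data")
  validate_session(out)
  out
}

#' Validate the session schema
#'
#' Checks the invariants shared by synthetic and disk-read sessions: every
#' trial has a choice, spike times are sorted within trial and lie inside
#' the trial epoch, and metadata is complete for every spiking unit.
#'
#' @param session A `session_data` object.
#' @return `session`, invisibly; errors on violation.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "session_data"))
  tr <- session$trials
  need <- c("trial_id", "stimulus", "choice", "correct", "withdrawal_ms")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(tr$choice) || !all(tr$choice %in% c("left", "right")))
    stop("every trial must have a left/right choice")
  sp <- session$spikes
  if (nrow(sp)) {
    if (!all(sp$trial_id %in% tr$trial_id))
      stop("spike table references unknown trial ids")
    if (any(sp$time_ms < TRIAL_EPOCH_MS[1] - 1e-9) ||
        any(sp$time_ms > TRIAL_EPOCH_MS[2] + 1e-9))
      stop("spike times outside the trial epoch")
    key <- paste(sp$unit_id, sp$trial_id)
    if (any(stats::ave(sp$time_ms, key, FUN = is.unsorted) > 0))
      stop("spike times must be sorted within trial")
    if (!all(unique(sp$unit_id) %in% session$units$unit_id))
      stop("spike table references units absent from metadata")
  }
  if (anyNA(session$units)) stop("unit metadata must be complete")
  invisible(session)
}

#' Stationary-Poisson calibration session
#'
#' Builds a session whose spike trains are statistically independent of
#' both stimulus identity and behavioral choice: a balanced trial table
#' (equal trials per stimulus, right/left choices alternating within each
#' stimulus) and units firing stationary Poisson trains at a common rate.
#' This is the null input for chance calibration of the stimulus decoder
#' (25%), the choice decoder (50%), and the temporal-modulation test
#' (5% false positives).
#'
#' @param n_units Number of units.
#' @param n_trials_per_stimulus Trials per stimulus.
#' @param rate_hz Constant firing rate of every unit.
#' @param seed Integer seed.
#' @param stimulus_set Named list of [sequence_spec()] (default the
#'   FFF/FMS/SMF/SSS library set).
#' @return A `session_data` with ground-truth class `"Unmodulated"`.
#' @export
stationary_poisson_session <- function(n_units = 100,
                                       n_trials_per_stimulus = 100,
                                       rate_hz = 10, seed = 1L,
                                       stimulus_set = NULL) {
  if (is.null(stimulus_set))
    stimulus_set <- sequence_library()[c("FFF", "FMS", "SMF", "SSS")]
  stim <- rep(names(stimulus_set), each = n_trials_per_stimulus)
  n <- length(stim)
  trials <- data.frame(
    trial_id = seq_len(n), stimulus = stim,
    choice = rep(rep(c("right", "left"),
                     length.out = n_trials_per_stimulus),
                 length(stimulus_set)),
    correct = TRUE, withdrawal_ms = 190)
  arch <- unit_archetype("Unmodulated", baseline_hz = rate_hz)
  seeds <- child_seeds(seed, n_units)
  spikes <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    sp <- simulate_unit(arch, trials, stimulus_set, seed = seeds[u])
    if (nrow(sp)) cbind(unit_id = sprintf("u%03d", u), sp) else NULL
  }))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(0), trial_id = integer(0),
                         time_ms = numeric(0))
  units <- data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
                      depth_um = 700, width_ms = 0.5, snr = 3,
                      isi_violation = 0.001, sort_class = "single",
                      spike_class = "RS", layer = "L4",
                      baseline_hz = rate_hz, true_class = "Unmodulated")
  session_data(trials, spikes, units, stimulus_set)
}

#' Spike times of one unit as a per-trial list
#'
#' @param session A `session_data`.
#' @param unit_id Unit identifier.
#' @param trials Optional subset of the trial table (defaults to all trials).
#' @return Named list (by trial id) of numeric spike-time vectors, including
#'   empty vectors for spikeless trials.
#' @export
unit_spike_list <- function(session, unit_id, trials = session$trials) {
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  out <- split(sp$time_ms, factor(sp$trial_id, levels = trials$trial_id))
  lapply(out, as.numeric)
}
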