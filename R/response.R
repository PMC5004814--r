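# Response analysis: PSTHs, the temporal-modulation permutation test,
# impulse-evoked response metrics, paired-pulse adaptation ratios, and
# choice-related firing (per-unit bias and sliding-t divergence time).
#
# Spike input is a per-trial list of spike-time vectors (ms, aligned to
# sequence onset) as produced by unit_spike_list().

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate on a regular bin grid. Optional boxcar
#' smoothing (for display and peak-latency extraction) convolves the rate
#' with a unit-mass boxcar, zero-padded at the edges, which preserves the
#' time-integral of rate away from the epoch edges.
#'
#' @param spike_list List of per-trial spike-time vectors (ms).
#' @param bin_ms Bin width (default 1 ms).
#' @param smoothing_ms Boxcar width in ms; 0 = none.
#' @param epoch_ms Length-2 analysis epoch (default the full trial epoch).
#' @return Object of class `psth`: list with `bin_edges_ms`, `rate_hz`,
#'   `n_trials`, `smoothing_ms`.
#' @export
compute_psth <- function(spike_list, bin_ms = 1, smoothing_ms = 0,
                         epoch_ms = TRIAL_EPOCH_MS) {
  if (!is.list(spike_list) || length(spike_list) < 1L)
    stop("spike_list must be a non-empty list of per-trial spike times")
  n_trials <- length(spike_list)
  edges <- seq(epoch_ms[1], epoch_ms[2], by = bin_ms)
  all_t <- unlist(spike_list, use.names = FALSE)
  all_t <- all_t[all_t >= edges[1] & all_t < edges[length(edges)]]
  counts <- if (length(all_t))
    tabulate(findInterval(all_t, edges), nbins = length(edges) - 1)
  else rep(0L, length(edges) - 1)
  rate <- counts / (n_trials * bin_ms / 1000)
  if (smoothing_ms > 0) rate <- .boxcar(rate, max(1L, round(smoothing_ms / bin_ms)))
  structure(list(bin_edges_ms = edges, rate_hz = rate, n_trials = n_trials,
                 smoothing_ms = smoothing_ms), class = "psth")
}

## zero-padded unit-mass boxcar smoothing with an effective width of k bins;
## even k uses a symmetric length-(k+1) kernel with half-weight endpoints so
## the smoother introduces no half-bin shift
.boxcar <- function(x, k) {
  if (k <= 1) return(x)
  kern <- if (k %% 2 == 1) rep(1 / k, k) else c(0.5, rep(1, k - 1), 0.5) / k
  n <- length(x)
  pad <- c(rep(0, length(kern)), x, rep(0, length(kern)))
  sm <- stats::filter(pad, kern, sides = 2)
  as.numeric(sm[(length(kern) + 1):(length(kern) + n)])
}

#' Permutation test for temporal modulation of firing rate
#'
#' Compares the observed binned rate profile over the analysis epoch with
#' profiles built from spike times re-drawn uniformly within the epoch
#' (preserving per-trial spike counts, destroying all timing). The test
#' statistic is the sum over bins of squared deviations of the binned rate
#' from the epoch-mean rate. The p-value uses the add-one permutation rule,
#' so the test is exact; a unit is "temporally modulated" at p < 0.05.
#'
#' @param spike_list List of per-trial spike-time vectors (ms).
#' @param epoch_ms Analysis epoch (default 0-180 ms).
#' @param bin_ms Comparison bin width (default 10 ms).
#' @param n_perm Number of permutations (default 10000; must be >= 1).
#' @param seed Optional seed for the permutation draws.
#' @return List with `p_value`, `statistic`, `n_spikes`, `modulated`
#'   (p < 0.05).
#' @export
temporal_modulation_test <- function(spike_list, epoch_ms = c(0, 180),
                                     bin_ms = 10, n_perm = 10000,
                                     seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  n_trials <- length(spike_list)
  edges <- seq(epoch_ms[1], epoch_ms[2], by = bin_ms)
  nb <- length(edges) - 1
  all_t <- unlist(spike_list, use.names = FALSE)
  all_t <- all_t[all_t >= epoch_ms[1] & all_t < epoch_ms[2]]
  n_sp <- length(all_t)
  if (n_sp == 0)
    return(list(p_value = 1, statistic = 0, n_spikes = 0L, modulated = FALSE))
  to_rate <- 1 / (n_trials * bin_ms / 1000)
  obs_counts <- tabulate(findInterval(all_t, edges), nbins = nb)
  stat <- function(counts) sum((counts * to_rate - mean(counts * to_rate))^2)
  obs <- stat(obs_counts)
  null_stats <- with_seed(seed, {
    # uniform re-draw of each spike's time within the epoch, all
    # permutations at once
    t_new <- stats::runif(n_sp * n_perm, epoch_ms[1], epoch_ms[2])
    b <- findInterval(t_new, edges)
    perm <- rep(seq_len(n_perm), each = n_sp)
    cnt <- tabulate(b + (perm - 1L) * nb, nbins = nb * n_perm)
    cmat <- matrix(cnt, nrow = nb)
    r <- cmat * to_rate
    colSums((r - rep(colMeans(r), each = nb))^2)
  })
  p <- (1 + sum(null_stats >= obs)) / (1 + n_perm)
  list(p_value = p, statistic = obs, n_spikes = n_sp, modulated = p < 0.05)
}

#' Impulse-evoked response metrics
#'
#' Baseline is the mean rate 0-10 ms before pulse onset. The peak
#' modulation is the signed extremum (maximum deviation above or below
#' baseline) of the 10-ms-smoothed PSTH in a 40-ms window after pulse
#' onset, and the latency is the time of that extremum. The mean evoked
#' rate is the unsmoothed rate 5-35 ms after onset minus baseline.
#' Significance is a paired t-test across trials of the per-trial evoked-
#' versus baseline-window rates.
#'
#' @param spike_list List of per-trial spike-time vectors (ms).
#' @param pulse_onset_ms Onset of the impulse (ms).
#' @param search_ms Peak search window length (default 40 ms).
#' @param smoothing_ms Boxcar width for the peak search (default 10 ms).
#' @param epoch_ms Trial epoch the spikes live in.
#' @return Object of class `evoked_response`: `baseline_hz`,
#'   `peak_modulation_hz` (signed), `peak_latency_ms` (relative to onset),
#'   `mean_evoked_hz`, `p_value`, `significant`.
#' @export
evoked_response <- function(spike_list, pulse_onset_ms, search_ms = 40,
                            smoothing_ms = 10, epoch_ms = TRIAL_EPOCH_MS) {
  if (pulse_onset_ms - 10 < epoch_ms[1] ||
      pulse_onset_ms + search_ms > epoch_ms[2])
    stop("baseline/search windows fall outside the trial epoch")
  raw <- compute_psth(spike_list, bin_ms = 1, smoothing_ms = 0, epoch_ms = epoch_ms)
  sm <- compute_psth(spike_list, bin_ms = 1, smoothing_ms = smoothing_ms,
                     epoch_ms = epoch_ms)
  centers <- raw$bin_edges_ms[-length(raw$bin_edges_ms)]
  base_idx <- centers >= pulse_onset_ms - 10 & centers < pulse_onset_ms
  baseline <- mean(raw$rate_hz[base_idx])
  search_idx <- which(centers >= pulse_onset_ms &
                        centers < pulse_onset_ms + search_ms)
  dev <- sm$rate_hz[search_idx] - baseline
  # boxcar smoothing can flatten the extremum into a plateau; report the
  # plateau midpoint as the latency
  cand <- which(abs(dev) >= max(abs(dev)) - 1e-9)
  k <- cand[ceiling(length(cand) / 2)]
  peak_mod <- dev[k]
  latency <- centers[search_idx[k]] - pulse_onset_ms
  evoked_idx <- centers >= pulse_onset_ms + 5 & centers < pulse_onset_ms + 35
  mean_evoked <- mean(raw$rate_hz[evoked_idx]) - baseline
  # per-trial paired comparison
  per_trial <- vapply(spike_list, function(st) {
    ev <- sum(st >= pulse_onset_ms + 5 & st < pulse_onset_ms + 35) / 0.030
    ba <- sum(st >= pulse_onset_ms - 10 & st < pulse_onset_ms) / 0.010
    c(ev, ba)
  }, numeric(2))
  d <- per_trial[1, ] - per_trial[2, ]
  p <- if (length(d) > 1 && stats::sd(d) > 0)
    stats::t.test(per_trial[1, ], per_trial[2, ], paired = TRUE)$p.value
  else 1
  structure(list(baseline_hz = baseline, peak_modulation_hz = peak_mod,
                 peak_latency_ms = latency, mean_evoked_hz = mean_evoked,
                 p_value = p, significant = p < 0.05),
            class = "evoked_response")
}

#' Paired-pulse adaptation ratios
#'
#' @param evoked_by_pulse Numeric vector of mean evoked rates, one per pulse
#'   position (pulse 1 first).
#' @return Ratios pulse N / pulse 1 for N = 2..n, or all-`NA` if the pulse-1
#'   rate is not positive (the unit is then excluded from population
#'   summaries).
#' @export
adaptation_ratio <- function(evoked_by_pulse) {
  n <- length(evoked_by_pulse)
  if (n < 2) stop("need evoked rates for at least two pulses")
  if (is.na(evoked_by_pulse[1]) || evoked_by_pulse[1] <= 0)
    return(rep(NA_real_, n - 1))
  evoked_by_pulse[-1] / evoked_by_pulse[1]
}

#' Population summary of adaptation ratios
#'
#' @param ratio_matrix Matrix of per-unit ratios (units in rows, pulse
#'   positions 2..n in columns); `NA` rows are excluded position-wise.
#' @return Data frame with `pulse`, `mean`, `sem`, `n`.
#' @export
adaptation_summary <- function(ratio_matrix) {
  ratio_matrix <- as.matrix(ratio_matrix)
  data.frame(
    pulse = seq_len(ncol(ratio_matrix)) + 1,
    mean = colMeans(ratio_matrix, na.rm = TRUE),
    sem = apply(ratio_matrix, 2, function(x) sem(x[!is.na(x)])),
    n = colSums(!is.na(ratio_matrix)))
}

## per-trial firing rate (Hz) in a window that may depend on the trial's
## stimulus: onset_by_stim is a scalar or named vector of window anchors.
.trial_rates <- function(spike_list, trials, onset_by_stim, window_ms) {
  onsets <- if (length(onset_by_stim) == 1L && is.null(names(onset_by_stim)))
    rep(onset_by_stim, nrow(trials))
  else unname(onset_by_stim[trials$stimulus])
  lo <- onsets + window_ms[1]; hi <- onsets + window_ms[2]
  vapply(seq_along(spike_list), function(i)
    sum(spike_list[[i]] >= lo[i] & spike_list[[i]] < hi[i]) /
      ((window_ms[2] - window_ms[1]) / 1000),
    numeric(1))
}

#' Choice-related firing bias of one unit
#'
#' Mean firing rate on right-choice minus left-choice trials in a window
#' after the final impulse onset (default 5-50 ms after onset).
#'
#' @param spike_list Per-trial spike times for the unit (same order as
#'   `trials`).
#' @param trials Trial table with `stimulus` and `choice`.
#' @param final_pulse_onset_ms Scalar, or named vector of final-impulse
#'   onsets per stimulus (onsets differ between sequences).
#' @param window_ms Window relative to the final-impulse onset.
#' @return List with `bias_hz` (right minus left), `mean_right_hz`,
#'   `mean_left_hz`, `n_right`, `n_left`; `bias_hz` is `NA` if either choice
#'   class has no trials.
#' @export
choice_bias <- function(spike_list, trials, final_pulse_onset_ms,
                        window_ms = c(5, 50)) {
  stopifnot(length(spike_list) == nrow(trials))
  r <- trials$choice == "right"
  rates <- .trial_rates(spike_list, trials, final_pulse_onset_ms, window_ms)
  if (!any(r) || all(r))
    return(list(bias_hz = NA_real_, mean_right_hz = NA_real_,
                mean_left_hz = NA_real_, n_right = sum(r),
                n_left = sum(!r)))
  list(bias_hz = mean(rates[r]) - mean(rates[!r]),
       mean_right_hz = mean(rates[r]), mean_left_hz = mean(rates[!r]),
       n_right = sum(r), n_left = sum(!r))
}

#' Population test of choice-related firing
#'
#' Computes each unit's mean rate on right- and left-choice trials in the
#' post-final-impulse window and tests the population with a paired t-test
#' across units. The same comparison on a pre-sequence baseline window of
#' the same trials serves as the control.
#'
#' @param session A `session_data`.
#' @param final_pulse_onset_ms Named vector of final-impulse onsets per
#'   stimulus (defaults to the session's stimuli).
#' @param unit_ids Units to include (default all).
#' @param window_ms Response window relative to final-impulse onset.
#' @param baseline_ms Absolute baseline window (default -25-0 ms).
#' @return List with `per_unit` (data frame of right/left rates and bias),
#'   `p_value`, `baseline_p_value`, `mean_bias_hz`.
#' @export
population_choice_bias <- function(session, final_pulse_onset_ms = NULL,
                                   unit_ids = NULL, window_ms = c(5, 50),
                                   baseline_ms = c(-25, 0)) {
  if (is.null(final_pulse_onset_ms))
    final_pulse_onset_ms <- vapply(session$stimuli, function(s)
      max(pulse_onsets(s)), numeric(1))
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  tr <- session$trials
  r <- tr$choice == "right"
  if (!any(r) || all(r)) stop("both choices must be present")
  rows <- lapply(unit_ids, function(uid) {
    sl <- unit_spike_list(session, uid, tr)
    resp <- .trial_rates(sl, tr, final_pulse_onset_ms, window_ms)
    base <- .trial_rates(sl, tr, 0, baseline_ms)
    data.frame(unit_id = uid,
               right_hz = mean(resp[r]), left_hz = mean(resp[!r]),
               base_right_hz = mean(base[r]), base_left_hz = mean(base[!r]))
  })
  per_unit <- do.call(rbind, rows)
  per_unit$bias_hz <- per_unit$right_hz - per_unit$left_hz
  paired_p <- function(a, b) {
    d <- a - b
    if (length(d) > 1 && stats::sd(d) > 0)
      stats::t.test(a, b, paired = TRUE)$p.value else 1
  }
  list(per_unit = per_unit,
       p_value = paired_p(per_unit$right_hz, per_unit$left_hz),
       baseline_p_value = paired_p(per_unit$base_right_hz,
                                   per_unit$base_left_hz),
       mean_bias_hz = mean(per_unit$bias_hz))
}

#' Divergence time of right- versus left-choice population rates
#'
#' Slides a window over the trial and, at each position, compares per-unit
#' windowed rates on right- versus left-choice trials with a paired t-test
#' across units. The divergence time is the start of the earliest window
#' from which p < alpha holds for `persist` consecutive windows.
#'
#' @param right_rates,left_rates Matrices (units x time bins) of per-unit
#'   PSTH rates for right- and left-choice trials on a common bin grid.
#' @param bin_edges_ms Bin edges of the rate matrices.
#' @param window_ms Sliding window length (default 10 ms).
#' @param step_ms Step between window starts (default 5 ms).
#' @param alpha Significance level (default 0.05).
#' @param persist Number of consecutive significant windows required
#'   (default 3; 1 reduces to the first significant window).
#' @return List with `window_start_ms`, `p_values`, `divergence_ms`
#'   (`NA` if no sustained divergence).
#' @export
divergence_time <- function(right_rates, left_rates, bin_edges_ms,
                            window_ms = 10, step_ms = 5, alpha = 0.05,
                            persist = 3) {
  stopifnot(is.matrix(right_rates), is.matrix(left_rates),
            all(dim(right_rates) == dim(left_rates)))
  if (nrow(right_rates) < 2) stop("need at least two units")
  centers <- bin_edges_ms[-length(bin_edges_ms)]
  t0 <- bin_edges_ms[1]; t1 <- bin_edges_ms[length(bin_edges_ms)]
  starts <- seq(t0, t1 - window_ms, by = step_ms)
  p <- vapply(starts, function(s) {
    idx <- centers >= s & centers < s + window_ms
    a <- rowMeans(right_rates[, idx, drop = FALSE])
    b <- rowMeans(left_rates[, idx, drop = FALSE])
    if (stats::sd(a - b) == 0) return(1)
    stats::t.test(a, b, paired = TRUE)$p.value
  }, numeric(1))
  sig <- p < alpha
  div <- NA_real_
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= persist)
  if (length(hit))
    div <- starts[ends[hit[1]] - run$lengths[hit[1]] + 1]
  list(window_start_ms = starts, p_values = p, divergence_ms = div)
}
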