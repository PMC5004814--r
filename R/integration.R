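# Integration-window regression: for each unit, ordinary least squares of
# 5-ms-binned firing rate on panel speed integrated over candidate windows
# W = 5, 10, ..., 180 ms, Bonferroni selection of the best window, and the
# Fast / Medium / SlowPos / SlowNeg unit classification.

WINDOW_GRID_MS <- seq(5, 180, by = 5)

#' Fit the 36 integration-window regressions for one unit
#'
#' Stacks the 5-ms-binned trial-averaged rates of all stimuli (4 stimuli x
#' 36 bins = 144 observations by default) and regresses them on the
#' integrated-speed regressor for each candidate window W. Slopes are in Hz
#' per mm of integrated panel travel.
#'
#' @param rates_by_stimulus Named list of numeric rate vectors (Hz), one per
#'   stimulus, binned at `bin_ms` over `epoch_ms`.
#' @param waveforms Named list of `waveform` objects for the same stimuli
#'   (names must match).
#' @param bin_ms Rate bin width (default 5 ms).
#' @param epoch_ms Analysis epoch (default 0-180 ms).
#' @param regressors Optional precomputed output of
#'   [build_regressor_matrices()] for these waveforms.
#' @return Object of class `window_regression`: data frame with one row per
#'   window (`W_ms`, `slope`, `intercept`, `r2`, `p`, `valid`).
#' @export
fit_window_regressions <- function(rates_by_stimulus, waveforms, bin_ms = 5,
                                   epoch_ms = c(0, 180), regressors = NULL) {
  stims <- names(rates_by_stimulus)
  if (is.null(stims) || !all(stims %in% names(waveforms)))
    stop("rates_by_stimulus and waveforms must share stimulus names")
  if (is.null(regressors))
    regressors <- build_regressor_matrices(waveforms[stims], bin_ms, epoch_ms)
  y <- unlist(rates_by_stimulus[stims], use.names = FALSE)
  nb <- (epoch_ms[2] - epoch_ms[1]) / bin_ms
  if (length(y) != nb * length(stims))
    stop(sprintf("each stimulus needs %d rate bins", nb))
  out <- data.frame(W_ms = WINDOW_GRID_MS, slope = NA_real_,
                    intercept = NA_real_, r2 = NA_real_, p = NA_real_,
                    valid = FALSE)
  n <- length(y)
  for (i in seq_along(WINDOW_GRID_MS)) {
    x <- unlist(lapply(stims, function(s) regressors[[s]][i, ]),
                use.names = FALSE)
    sx <- stats::sd(x)
    if (sx == 0) next  # no panel motion: fit invalid for this window
    # closed-form simple OLS with the F-test of the slope
    mx <- mean(x); my <- mean(y)
    sxy <- sum((x - mx) * (y - my)); sxx <- sum((x - mx)^2)
    slope <- sxy / sxx
    intercept <- my - slope * mx
    sst <- sum((y - my)^2)
    r2 <- if (sst > 0) slope * sxy / sst else 0
    p <- if (sst > 0 && r2 < 1) {
      f <- (n - 2) * r2 / (1 - r2)
      stats::pf(f, 1, n - 2, lower.tail = FALSE)
    } else if (sst == 0) 1 else 0
    out[i, c("slope", "intercept", "r2", "p")] <- c(slope, intercept, r2, p)
    out$valid[i] <- TRUE
  }
  class(out) <- c("window_regression", "data.frame")
  out
}

#' Precompute integrated-speed regressors for a set of stimuli
#'
#' @param waveforms Named list of `waveform` objects.
#' @param bin_ms Rate bin width.
#' @param epoch_ms Analysis epoch.
#' @return Named list of matrices (windows x bins) of regressor values.
#' @export
build_regressor_matrices <- function(waveforms, bin_ms = 5,
                                     epoch_ms = c(0, 180)) {
  lapply(waveforms, function(w)
    t(vapply(WINDOW_GRID_MS, function(W)
      integrated_speed_regressor(w, W, bin_ms, epoch_ms),
      numeric((epoch_ms[2] - epoch_ms[1]) / bin_ms))))
}

#' Select the best integration window under Bonferroni correction
#'
#' Candidate windows are those with a regression p-value below
#' `alpha_family / 36` (0.05 / 36 = 0.0014). Among candidates, the best
#' window maximizes R^2; exact ties go to the smallest window.
#'
#' @param fits A `window_regression` from [fit_window_regressions()].
#' @param alpha_family Family-wise significance level (default 0.05).
#' @return List with `best_W` (NA if no candidate), `slope`, `slope_sign`,
#'   `r2`, `p`, and `alpha_per_test`.
#' @export
select_best_window <- function(fits, alpha_family = 0.05) {
  stopifnot(inherits(fits, "window_regression"), nrow(fits) == 36L)
  alpha <- alpha_family / nrow(fits)
  cand <- which(fits$valid & !is.na(fits$p) & fits$p < alpha)
  if (!length(cand))
    return(list(best_W = NA_real_, slope = NA_real_, slope_sign = NA_real_,
                r2 = NA_real_, p = NA_real_, alpha_per_test = alpha))
  best <- cand[which.max(fits$r2[cand])]   # first max: smallest W on ties
  list(best_W = fits$W_ms[best], slope = fits$slope[best],
       slope_sign = sign(fits$slope[best]), r2 = fits$r2[best],
       p = fits$p[best], alpha_per_test = alpha)
}

#' Classify a unit from its best integration window and slope sign
#'
#' Fast: best window 5-20 ms; Medium: 25-50 ms; Slow: 55-180 ms, split by
#' slope sign into SlowPos / SlowNeg (55 ms is assigned to Slow); no
#' significant window: Unclassified.
#'
#' @param best_W Best window in ms, or NA.
#' @param slope_sign Sign of the regression slope at the best window.
#' @return One of `"Fast"`, `"Medium"`, `"SlowPos"`, `"SlowNeg"`,
#'   `"Unclassified"`.
#' @export
classify_unit <- function(best_W, slope_sign) {
  if (is.na(best_W)) return("Unclassified")
  if (!best_W %in% WINDOW_GRID_MS) stop("best_W must lie on the 5-ms grid")
  if (best_W <= 20) "Fast"
  else if (best_W < 55) "Medium"
  else if (slope_sign >= 0) "SlowPos"
  else "SlowNeg"
}

#' Per-stimulus binned PSTH vectors for one unit
#'
#' Trial-averaged rates over all trials of each stimulus (both choices
#' pooled), binned for the window regression.
#'
#' @param session A `session_data`.
#' @param unit_id Unit identifier.
#' @param bin_ms Bin width (default 5 ms).
#' @param epoch_ms Analysis epoch (default 0-180 ms).
#' @return Named list of rate vectors, one per stimulus.
#' @export
unit_psth_by_stimulus <- function(session, unit_id, bin_ms = 5,
                                  epoch_ms = c(0, 180)) {
  out <- lapply(names(session$stimuli), function(s) {
    tr <- session$trials[session$trials$stimulus == s, , drop = FALSE]
    sl <- unit_spike_list(session, unit_id, tr)
    compute_psth(sl, bin_ms = bin_ms, epoch_ms = epoch_ms)$rate_hz
  })
  names(out) <- names(session$stimuli)
  out
}

#' Run the window regression and classification for every unit
#'
#' @param session A `session_data`.
#' @param alpha_family Family-wise level for window selection.
#' @param dt_ms Waveform sampling step.
#' @param unit_ids Units to classify (default all).
#' @return Data frame with `unit_id`, `best_W`, `slope`, `r2`, `p`,
#'   `class`; one row per unit.
#' @export
classify_session_units <- function(session, alpha_family = 0.05,
                                   dt_ms = 0.5, unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  waveforms <- lapply(session$stimuli, build_sequence, dt_ms = dt_ms)
  regs <- build_regressor_matrices(waveforms)
  rows <- lapply(unit_ids, function(uid) {
    rates <- unit_psth_by_stimulus(session, uid)
    fits <- fit_window_regressions(rates, waveforms, regressors = regs)
    sel <- select_best_window(fits, alpha_family)
    data.frame(unit_id = uid, best_W = sel$best_W, slope = sel$slope,
               r2 = sel$r2, p = sel$p,
               class = classify_unit(sel$best_W, sel$slope_sign))
  })
  do.call(rbind, rows)
}
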