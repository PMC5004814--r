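# Behavioral summaries: per-stimulus choice fractions, bias-corrected
# relative right choice, d-prime discriminability, the FMS/SMF proportion
# test, and the fixed-panel comparison measure.

#' Summarize a behavioral session
#'
#' Relative right choice is each stimulus' right-choice fraction minus the
#' unweighted mean fraction across stimuli, removing side bias. The simple
#' discrimination measure is the right-choice fraction to the fastest
#' stimulus minus that to the slowest (FFF - SSS by default).
#'
#' @param trials Trial table with `stimulus` and `choice` columns.
#' @param hit_stimulus,fa_stimulus Stimuli treated as signal and noise for
#'   d-prime and the simple discrimination measure (default `"FFF"` vs
#'   `"SSS"`; falls back to `"FSFS"` vs `"SFFS"` when present).
#' @return List of class `behavior_summary`: per-stimulus `n` and
#'   `fraction_right`, `relative_right` (sums to 0), `dprime`,
#'   `fms_smf_p` (`NA` unless both FMS and SMF are present),
#'   `simple_discrimination`.
#' @export
summarize_behavior <- function(trials, hit_stimulus = NULL,
                               fa_stimulus = NULL) {
  if (!all(c("stimulus", "choice") %in% names(trials)))
    stop("trials must have stimulus and choice columns")
  stims <- sort(unique(trials$stimulus))
  n <- vapply(stims, function(s) sum(trials$stimulus == s), numeric(1))
  if (any(n < 1)) stop("need at least one trial per stimulus")
  fr <- vapply(stims, function(s)
    mean(trials$choice[trials$stimulus == s] == "right"), numeric(1))
  rel <- fr - mean(fr)
  if (is.null(hit_stimulus))
    hit_stimulus <- if ("FFF" %in% stims) "FFF"
                    else if ("FSFS" %in% stims) "FSFS" else stims[1]
  if (is.null(fa_stimulus))
    fa_stimulus <- if ("SSS" %in% stims) "SSS"
                   else if ("SFFS" %in% stims) "SFFS" else stims[length(stims)]
  dp <- if (all(c(hit_stimulus, fa_stimulus) %in% stims))
    dprime(fr[[hit_stimulus]], fr[[fa_stimulus]],
           n[[hit_stimulus]], n[[fa_stimulus]])
  else NA_real_
  simple <- if (all(c(hit_stimulus, fa_stimulus) %in% stims))
    fr[[hit_stimulus]] - fr[[fa_stimulus]] else NA_real_
  p_fms <- if (all(c("FMS", "SMF") %in% stims))
    fms_smf_proportion_test(trials)$p_value else NA_real_
  structure(list(stimuli = stims, n = n, fraction_right = fr,
                 relative_right = rel, dprime = dp, fms_smf_p = p_fms,
                 simple_discrimination = simple),
            class = "behavior_summary")
}

#' Signal-detection discriminability (d-prime)
#'
#' Equal-variance Gaussian d' = z(hit) - z(false alarm), with rates clipped
#' to `[1/(2n), 1 - 1/(2n)]` before the normal quantile so that perfect
#' rates remain finite.
#'
#' @param hit_rate P(right | signal stimulus).
#' @param fa_rate P(right | noise stimulus).
#' @param n_hit,n_fa Trial counts behind each rate (> 0).
#' @return d-prime.
#' @export
dprime <- function(hit_rate, fa_rate, n_hit, n_fa) {
  if (n_hit <= 0 || n_fa <= 0) stop("counts must be positive")
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_hit)) - stats::qnorm(clip(fa_rate, n_fa))
}

#' Two-sample proportion test of FMS versus SMF right-choice fractions
#'
#' Two-sample z-test for proportions (chi-squared form without continuity
#' correction), Bonferroni-corrected across `n_comparisons` (default 8,
#' one per rat): significant iff p < 0.05 / n_comparisons = 0.00625.
#'
#' @param trials Trial table containing FMS and SMF trials.
#' @param n_comparisons Bonferroni family size (default 8).
#' @param stim_a,stim_b The two stimuli compared (default FMS vs SMF).
#' @return List with `p_value`, `threshold`, `significant`, and the two
#'   right-choice fractions.
#' @export
fms_smf_proportion_test <- function(trials, n_comparisons = 8,
                                    stim_a = "FMS", stim_b = "SMF") {
  a <- trials$choice[trials$stimulus == stim_a]
  b <- trials$choice[trials$stimulus == stim_b]
  if (!length(a) || !length(b))
    stop("both stimuli need at least one trial")
  x <- c(sum(a == "right"), sum(b == "right"))
  n <- c(length(a), length(b))
  pr <- x / n
  pooled <- sum(x) / sum(n)
  se <- sqrt(pooled * (1 - pooled) * (1 / n[1] + 1 / n[2]))
  p <- if (pr[1] == pr[2] || se == 0) 1
       else 2 * stats::pnorm(-abs((pr[1] - pr[2]) / se))
  thr <- 0.05 / n_comparisons
  list(p_value = p, threshold = thr, significant = p < thr,
       fraction_a = x[1] / n[1], fraction_b = x[2] / n[2])
}

#' Fixed-panel comparison of discrimination between condition blocks
#'
#' The simple difference measure applied to two condition blocks: the
#' change in (fraction right to the signal stimulus minus fraction right to
#' the noise stimulus) between normal and fixed-panel trials.
#'
#' @param trials_a,trials_b Trial tables for the two blocks (e.g. moving
#'   panel vs fixed panel).
#' @param hit_stimulus,fa_stimulus Signal/noise stimuli (default FFF/SSS).
#' @return List with `discrimination_a`, `discrimination_b`, `difference`.
#' @export
fixed_panel_comparison <- function(trials_a, trials_b,
                                   hit_stimulus = "FFF",
                                   fa_stimulus = "SSS") {
  disc <- function(tr) {
    fr <- function(s) mean(tr$choice[tr$stimulus == s] == "right")
    fr(hit_stimulus) - fr(fa_stimulus)
  }
  da <- disc(trials_a); db <- disc(trials_b)
  list(discrimination_a = da, discrimination_b = db, difference = da - db)
}
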