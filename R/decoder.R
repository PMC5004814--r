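# Population decoding: per-unit one-vs-all logistic classifiers of stimulus
# identity with equal-weight probability summation across units, the binary
# choice decoder, and the rate-normalized / time-scrambled controls.
#
# Each unit is an independent classifier over its binned single-trial spike
# counts; population predictions sum the per-unit normalized class
# probabilities, so every unit carries the same vote mass.

#' Binning specification for decoder spike counts
#'
#' Three modes: regular bins over a fixed window (e.g. 10-ms bins over
#' 0-150 ms), a single fixed bin over the window, or a single bin covering
#' the last `pre_withdrawal_ms` before the trial's nose-poke withdrawal.
#'
#' @param bin_ms Bin width in ms, or `NULL` for a single bin.
#' @param window_ms Analysis window (default 0-150 ms).
#' @param pre_withdrawal_ms If non-`NULL`, use a single per-trial bin of
#'   this length ending at nose-poke withdrawal (overrides `window_ms`).
#' @return Object of class `bin_spec`.
#' @export
bin_spec <- function(bin_ms = 10, window_ms = c(0, 150),
                     pre_withdrawal_ms = NULL) {
  if (!is.null(bin_ms)) {
    nb <- (window_ms[2] - window_ms[1]) / bin_ms
    if (abs(nb - round(nb)) > 1e-9)
      stop("bin_ms must divide the analysis window")
  }
  structure(list(bin_ms = bin_ms, window_ms = window_ms,
                 pre_withdrawal_ms = pre_withdrawal_ms),
            class = "bin_spec")
}

.n_bins <- function(spec) {
  if (!is.null(spec$pre_withdrawal_ms)) return(1L)
  if (is.null(spec$bin_ms)) return(1L)
  as.integer(round((spec$window_ms[2] - spec$window_ms[1]) / spec$bin_ms))
}

#' Bin one spike train for decoding
#'
#' @param spike_times Spike times in ms, aligned to sequence onset.
#' @param spec A [bin_spec()].
#' @param withdrawal_ms Trial withdrawal time (required for
#'   pre-withdrawal specs).
#' @return Integer count vector (spikes outside the window are ignored).
#' @export
bin_spike_train <- function(spike_times, spec, withdrawal_ms = NULL) {
  stopifnot(inherits(spec, "bin_spec"))
  if (!is.null(spec$pre_withdrawal_ms)) {
    if (is.null(withdrawal_ms))
      stop("withdrawal_ms required for pre-withdrawal binning")
    lo <- withdrawal_ms - spec$pre_withdrawal_ms
    return(sum(spike_times >= lo & spike_times < withdrawal_ms))
  }
  w <- spec$window_ms
  if (is.null(spec$bin_ms))
    return(sum(spike_times >= w[1] & spike_times < w[2]))
  edges <- seq(w[1], w[2], by = spec$bin_ms)
  keep <- spike_times >= w[1] & spike_times < w[2]
  tabulate(findInterval(spike_times[keep], edges), nbins = length(edges) - 1)
}

#' Normalize a count vector to unit Euclidean norm
#'
#' Preserves the temporal pattern while removing overall rate; an all-zero
#' vector passes through unchanged.
#'
#' @param counts Numeric vector (or matrix: rows are normalized).
#' @return Normalized vector/matrix.
#' @export
rate_normalize <- function(counts) {
  if (is.matrix(counts)) return(t(apply(counts, 1, rate_normalize)))
  nrm <- sqrt(sum(counts^2))
  if (nrm == 0) counts else counts / nrm
}

#' Scramble spike times within trials
#'
#' Re-draws each spike's time uniformly within the epoch, preserving
#' per-trial spike counts and destroying temporal structure. Spikes outside
#' the epoch are left untouched.
#'
#' @param session A `session_data`.
#' @param epoch_ms Window within which spikes are scrambled
#'   (default 0-150 ms, the decoding window).
#' @param seed Seed for the redraw.
#' @return The session with scrambled spike times.
#' @export
time_scramble_session <- function(session, epoch_ms = c(0, 150), seed = 1L) {
  sp <- session$spikes
  inside <- sp$time_ms >= epoch_ms[1] & sp$time_ms < epoch_ms[2]
  sp$time_ms[inside] <- with_seed(seed,
    stats::runif(sum(inside), epoch_ms[1], epoch_ms[2]))
  o <- order(sp$unit_id, sp$trial_id, sp$time_ms)
  session$spikes <- sp[o, ]
  rownames(session$spikes) <- NULL
  session
}

## ---- penalized logistic regression (IRLS, compiled) ----------------------

## Ridge-penalized logistic fit; X excludes the intercept, which is added
## internally and left unpenalized. Returns c(bias, coefficients).
.ridge_logistic <- function(X, y, lambda, max_iter = 30L, tol = 1e-8) {
  drop(ridge_logistic_cpp(cbind(1, X), y, lambda, max_iter, tol))
}

.logistic_prob <- function(b, X) stats::plogis(drop(cbind(1, X) %*% b))

## k-fold cross-validated choice of the ridge penalty (held-out binomial
## deviance); fold assignment uses the caller's RNG stream so results are
## reproducible under the run seed.
.cv_ridge_logistic <- function(X, y, lambdas, k = 5) {
  if (length(lambdas) == 1L) return(.ridge_logistic(X, y, lambdas))
  fold <- sample(rep_len(seq_len(k), length(y)))
  drop(cv_ridge_logistic_cpp(cbind(1, X), y, lambdas, fold))
}

## stratified train/test split of indices by label
.stratified_split <- function(labels, train_fraction) {
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(g) {
    n_tr <- max(1L, round(length(g) * train_fraction))
    sample(g, n_tr)
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(idx, train)))
}

#' Fit a one-vs-all stimulus classifier for one unit
#'
#' Four one-vs-rest logistic functions (one per stimulus) fit by
#' ridge-penalized logistic regression on a stratified training subset of
#' trials; 5-fold cross-validation within the training split selects the
#' penalty. Predicted class probabilities are renormalized to sum to 1 per
#' trial so every unit carries equal weight in population decoding.
#'
#' @param counts Matrix of binned spike counts (trials x bins).
#' @param labels Class label per trial (4 stimuli, or any >= 2 classes).
#' @param train_fraction Fraction of trials used for fitting (default 0.70).
#' @param lambdas Candidate ridge penalties for cross-validation.
#' @param cv_folds Folds for penalty selection.
#' @param seed Optional seed (split and cross-validation folds).
#' @return Object of class `unit_decoder` with coefficient matrix
#'   (classes x bins + 1), class levels, and the train/test indices.
#' @export
fit_unit_ova <- function(counts, labels, train_fraction = 0.70,
                         lambdas = c(0.01, 0.1, 1, 10, Inf), cv_folds = 5,
                         seed = NULL) {
  counts <- as.matrix(counts)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes present")
  with_seed(seed, {
    repeat {
      split <- .stratified_split(labels, train_fraction)
      if (all(classes %in% labels[split$train])) break
    }
    Xtr <- counts[split$train, , drop = FALSE]
    coef <- t(vapply(classes, function(cl)
      .cv_ridge_logistic(Xtr, as.numeric(labels[split$train] == cl),
                         lambdas, cv_folds),
      numeric(ncol(counts) + 1)))
    structure(list(coef = coef, classes = classes, train = split$train,
                   test = split$test),
              class = "unit_decoder")
  })
}

#' Per-class probabilities from one unit's decoder
#'
#' @param decoder A `unit_decoder`.
#' @param counts Count vector, or matrix (trials x bins).
#' @return Matrix (trials x classes) of probabilities normalized to sum to
#'   1 within each trial.
#' @export
predict_unit <- function(decoder, counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1)
  raw <- vapply(seq_len(nrow(decoder$coef)), function(i)
    .logistic_prob(decoder$coef[i, ], counts), numeric(nrow(counts)))
  raw <- matrix(raw, nrow = nrow(counts))
  s <- rowSums(raw)
  s[s == 0] <- 1
  p <- raw / s
  colnames(p) <- decoder$classes
  p
}

## argmax with uniform random tie-breaking
.argmax_random <- function(x) {
  m <- which(x >= max(x) - 1e-12)
  if (length(m) == 1L) m else sample(m, 1L)
}

#' Population prediction from one spike train per unit
#'
#' Sums the normalized class probabilities of every unit's decoder for its
#' supplied single-trial count vector and returns the class with maximal
#' summed probability (ties broken uniformly at random).
#'
#' @param decoders List of `unit_decoder` objects.
#' @param trains List of count vectors, one per decoder.
#' @return The predicted class label.
#' @export
predict_population <- function(decoders, trains) {
  if (!length(decoders)) stop("empty decoder set")
  stopifnot(length(decoders) == length(trains))
  total <- Reduce(`+`, lapply(seq_along(decoders), function(i)
    drop(predict_unit(decoders[[i]], trains[[i]]))))
  decoders[[1]]$classes[.argmax_random(total)]
}

## binned count matrices (trials x bins) for each unit in trial-table order
.session_counts <- function(session, spec, unit_ids) {
  tr <- session$trials
  nb <- .n_bins(spec)
  lapply(unit_ids, function(uid) {
    sl <- unit_spike_list(session, uid, tr)
    cm <- vapply(seq_along(sl), function(i)
      as.numeric(bin_spike_train(sl[[i]], spec, tr$withdrawal_ms[i])),
      numeric(nb))
    if (nb == 1L) matrix(cm, ncol = 1) else t(cm)
  })
}

#' Evaluate the four-way population stimulus decoder
#'
#' Per repeat: a fresh stratified 70/30 split of trials (shared across
#' units), per-unit one-vs-all fits on the training split, and population
#' predictions on held-out trials. Each test event queries one class; every
#' unit contributes one count vector drawn without replacement from its
#' held-out trials of that class, so units' trains are decoupled as in the
#' independent-unit model. Confusion counts accumulate over repeats.
#'
#' @param session A `session_data`.
#' @param spec A [bin_spec()] (default 10-ms bins over 0-150 ms).
#' @param n_repeats Number of fit/decode repetitions (default 300).
#' @param train_fraction Training fraction (default 0.70).
#' @param control `"none"` or `"rate_norm"` (Euclidean-norm normalization
#'   of every count vector); time-scrambling is applied to the session via
#'   [time_scramble_session()] before calling this.
#' @param unit_ids Units to include (default all).
#' @param lambdas,cv_folds Ridge-penalty candidates (Inf = intercept-only null model) and CV folds.
#' @param seed Seed for the whole evaluation.
#' @return Object of class `decoder_report`: confusion matrix (rows
#'   normalized to 1), `overall_pct`, `per_unit_pct`, `n_repeats`, `seed`.
#' @export
evaluate_stimulus_decoder <- function(session, spec = bin_spec(),
                                      n_repeats = 300,
                                      train_fraction = 0.70,
                                      control = c("none", "rate_norm"),
                                      unit_ids = NULL,
                                      lambdas = c(0.01, 0.1, 1, 10, Inf),
                                      cv_folds = 5, seed = 1L) {
  control <- match.arg(control)
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  labels <- session$trials$stimulus
  classes <- sort(unique(labels))
  if (any(table(labels) < 2)) stop("need >= 2 trials per class")
  counts <- .session_counts(session, spec, unit_ids)
  if (control == "rate_norm") counts <- lapply(counts, rate_normalize)
  n_units <- length(counts)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  unit_hits <- numeric(n_units); unit_events <- 0
  per_repeat_pct <- numeric(n_repeats)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      split <- .stratified_split(labels, train_fraction)
      decoders <- lapply(counts, function(cm)
        fit_unit_ova_prefit(cm[split$train, , drop = FALSE],
                            labels[split$train], lambdas, cv_folds))
      test <- split$test
      # per-unit class probabilities and own predictions for every held-out
      # trial, computed once per repeat
      p_test <- lapply(seq_len(n_units), function(u)
        predict_unit(decoders[[u]], counts[[u]][test, , drop = FALSE]))
      own_pred <- lapply(p_test, function(p)
        classes[max.col(p, ties.method = "random")])
      rep_hits <- 0; rep_events <- 0
      for (cl in classes) {
        rows <- which(labels[test] == cl)
        m <- length(rows)
        if (!m) next
        # each unit contributes held-out trials of this class in its own
        # random order (sampling without replacement)
        draws <- lapply(seq_len(n_units), function(u)
          if (m > 1) sample(rows) else rows)
        total <- Reduce(`+`, lapply(seq_len(n_units), function(u)
          p_test[[u]][draws[[u]], , drop = FALSE]))
        pred <- classes[max.col(total, ties.method = "random")]
        conf[cl, ] <- conf[cl, ] + tabulate(match(pred, classes),
                                            nbins = length(classes))
        unit_hits <- unit_hits + vapply(seq_len(n_units), function(u)
          sum(own_pred[[u]][draws[[u]]] == cl), numeric(1))
        unit_events <- unit_events + m
        rep_hits <- rep_hits + sum(pred == cl); rep_events <- rep_events + m
      }
      per_repeat_pct[rep_i] <- 100 * rep_hits / max(rep_events, 1)
    }
  })
  rep <- .decoder_report(conf, unit_hits / unit_events * 100, unit_ids,
                         n_repeats, seed)
  rep$per_repeat_pct <- per_repeat_pct
  rep
}

## OVA fit on an already-split training set (internal fast path)
fit_unit_ova_prefit <- function(Xtr, labels_tr, lambdas, cv_folds) {
  classes <- sort(unique(labels_tr))
  coef <- t(vapply(classes, function(cl)
    .cv_ridge_logistic(Xtr, as.numeric(labels_tr == cl), lambdas, cv_folds),
    numeric(ncol(Xtr) + 1)))
  structure(list(coef = coef, classes = classes), class = "unit_decoder")
}

.decoder_report <- function(conf, per_unit_pct, unit_ids, n_repeats, seed) {
  totals <- rowSums(conf)
  norm <- conf / ifelse(totals == 0, 1, totals)
  overall <- 100 * sum(diag(conf)) / sum(conf)
  structure(list(confusion = norm, counts = conf, overall_pct = overall,
                 per_unit_pct = stats::setNames(per_unit_pct, unit_ids),
                 n_repeats = n_repeats, seed = seed),
            class = "decoder_report")
}

#' Evaluate the binary population choice decoder
#'
#' A single logistic function per unit, trained on trials of all stimuli
#' pooled (stratified by stimulus x choice), then evaluated separately for
#' each stimulus on choice-balanced held-out sets so that 50% is a
#' meaningful chance level despite behavioral side bias.
#'
#' @param session A `session_data`.
#' @param spec A [bin_spec()]; the printed variants are the single 150-ms
#'   bin (`bin_spec(NULL)`) and the last 100 ms before withdrawal
#'   (`bin_spec(pre_withdrawal_ms = 100)`).
#' @param n_repeats Number of repetitions (default 300).
#' @param train_fraction Training fraction (default 0.70).
#' @param unit_ids Units to include (default all).
#' @param lambdas,cv_folds Ridge-penalty candidates (Inf = intercept-only null model) and CV folds.
#' @param seed Seed for the whole evaluation.
#' @return List of class `choice_decoder_report`: `per_stimulus_pct`
#'   (named accuracy vector, skipped stimuli `NA`), `mean_pct`,
#'   `n_repeats`, `seed`.
#' @export
evaluate_choice_decoder <- function(session, spec = bin_spec(NULL),
                                    n_repeats = 300, train_fraction = 0.70,
                                    unit_ids = NULL,
                                    lambdas = c(0.01, 0.1, 1, 10, Inf),
                                    cv_folds = 5, seed = 1L) {
  if (is.null(unit_ids)) unit_ids <- session$units$unit_id
  tr <- session$trials
  if (length(unique(tr$choice)) < 2) stop("both choices must be present")
  counts <- .session_counts(session, spec, unit_ids)
  n_units <- length(counts)
  stims <- sort(unique(tr$stimulus))
  strat <- paste(tr$stimulus, tr$choice)
  hits <- stats::setNames(numeric(length(stims)), stims)
  events <- stats::setNames(numeric(length(stims)), stims)
  per_repeat_pct <- rep(NA_real_, n_repeats)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      split <- .stratified_split(strat, train_fraction)
      y_tr <- as.numeric(tr$choice[split$train] == "right")
      if (length(unique(y_tr)) < 2) next
      coefs <- lapply(counts, function(cm)
        .cv_ridge_logistic(cm[split$train, , drop = FALSE], y_tr,
                           lambdas, cv_folds))
      # per-unit P(right) for every held-out trial, once per repeat
      p_right_test <- lapply(seq_len(n_units), function(u)
        .logistic_prob(coefs[[u]],
                       counts[[u]][split$test, , drop = FALSE]))
      rep_hits <- stats::setNames(numeric(length(stims)), stims)
      rep_events <- stats::setNames(numeric(length(stims)), stims)
      for (s in stims) {
        in_s <- tr$stimulus[split$test] == s
        right_rows <- which(in_s & tr$choice[split$test] == "right")
        left_rows <- which(in_s & tr$choice[split$test] == "left")
        n_bal <- min(length(right_rows), length(left_rows))
        if (n_bal < 1) next  # a choice class missing: stimulus skipped
        for (ch in c("right", "left")) {
          pool0 <- if (ch == "right") right_rows else left_rows
          pool <- if (length(pool0) > 1) sample(pool0, n_bal) else pool0
          draws <- lapply(seq_len(n_units), function(u)
            if (n_bal > 1) sample(pool) else pool)
          # summed P(right) across units for each balanced test event
          total <- Reduce(`+`, lapply(seq_len(n_units), function(u)
            p_right_test[[u]][draws[[u]]]))
          tied <- abs(total - n_units / 2) < 1e-12
          pred <- ifelse(total > n_units / 2, "right", "left")
          if (any(tied))
            pred[tied] <- sample(c("right", "left"), sum(tied),
                                 replace = TRUE)
          hits[s] <- hits[s] + sum(pred == ch)
          events[s] <- events[s] + n_bal
          rep_hits[s] <- rep_hits[s] + sum(pred == ch)
          rep_events[s] <- rep_events[s] + n_bal
        }
      }
      ok <- rep_events > 0
      if (any(ok))
        per_repeat_pct[rep_i] <- mean(100 * rep_hits[ok] / rep_events[ok])
    }
  })
  pct <- ifelse(events > 0, 100 * hits / events, NA_real_)
  structure(list(per_stimulus_pct = pct,
                 mean_pct = mean(pct, na.rm = TRUE),
                 per_repeat_pct = per_repeat_pct,
                 n_repeats = n_repeats, seed = seed),
            class = "choice_decoder_report")
}
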