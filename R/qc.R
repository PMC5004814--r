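# Post-sorting unit quality control and classification: interspike-interval
# criterion, waveform signal-to-noise, RS/FS spike-width split, and laminar
# assignment from recording depth.

#' Fraction of inter-spike intervals below the refractory criterion
#'
#' @param spike_times Pooled, sorted spike times in ms for one unit.
#' @param threshold_ms Refractory threshold (default 1.5 ms).
#' @return Fraction of consecutive intervals `< threshold_ms`. Single-unit
#'   eligibility requires the fraction to be strictly below 0.005. `NA` if
#'   fewer than two spikes (such a unit is treated as multi-unit).
#' @export
isi_violation_fraction <- function(spike_times, threshold_ms = 1.5) {
  if (length(spike_times) < 2L) return(NA_real_)
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  mean(diff(spike_times) < threshold_ms)
}

#' Classify a unit as regular- or fast-spiking by spike width
#'
#' @param width_ms Trough-to-peak delay of the mean waveform in ms.
#' @return `"FS"` iff width is strictly below 0.375 ms, else `"RS"`.
#' @export
classify_rs_fs <- function(width_ms) {
  if (any(width_ms <= 0)) stop("width_ms must be positive")
  ifelse(width_ms < 0.375, "FS", "RS")
}

.layer_bins <- data.frame(
  layer = c("L2/3", "L4", "L5A", "L5B", "L6"),
  lo = c(200, 650, 975, 1285, 1575),
  hi = c(650, 975, 1285, 1575, 2200))

#' Assign a cortical layer from recording depth
#'
#' Half-open, lower-closed laminar bins: L2/3 `[200, 650)`, L4 `[650, 975)`,
#' L5A `[975, 1285)`, L5B `[1285, 1575)`, L6 `[1575, 2200)`; anything outside
#' is `"out"` (boundary depths go to the deeper layer).
#'
#' @param depth_um Recording depth(s) in micrometres (>= 0).
#' @return Character vector of laminar labels.
#' @export
assign_layer <- function(depth_um) {
  if (any(depth_um < 0)) stop("depth_um must be >= 0")
  vapply(depth_um, function(d) {
    hit <- which(d >= .layer_bins$lo & d < .layer_bins$hi)
    if (length(hit)) .layer_bins$layer[hit] else "out"
  }, character(1))
}

#' Waveform signal-to-noise ratio
#'
#' @param trough_to_peak Trough-to-peak height of the mean spike waveform.
#' @param mean_noise_sd Average standard deviation across waveform samples
#'   (> 0).
#' @return The ratio. Single-unit inclusion requires a value strictly
#'   greater than 2.
#' @export
snr <- function(trough_to_peak, mean_noise_sd) {
  if (any(mean_noise_sd <= 0)) stop("mean_noise_sd must be positive")
  trough_to_peak / mean_noise_sd
}

#' Apply the full unit QC to a metadata table
#'
#' Evaluates the single-unit inclusion criteria (ISI violation fraction
#' < 0.005, SNR > 2) and derives the RS/FS and laminar labels. Verdicts are
#' pure functions of the metadata.
#'
#' @param units Data frame with columns `unit_id`, `depth_um`, `width_ms`,
#'   `snr`, `isi_violation`, `sort_class`.
#' @return The input with added columns `layer` (from depth), `spike_class`
#'   (from width), `qc_single` (logical: passes single-unit criteria),
#'   and `qc_reason` (`"pass"` or semicolon-separated failures).
#' @export
qc_units <- function(units) {
  need <- c("unit_id", "depth_um", "width_ms", "snr", "isi_violation")
  miss <- setdiff(need, names(units))
  if (length(miss)) stop("units table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- units
  out$layer <- assign_layer(units$depth_um)
  out$spike_class <- classify_rs_fs(units$width_ms)
  isi_ok <- !is.na(units$isi_violation) & units$isi_violation < 0.005
  snr_ok <- units$snr > 2
  out$qc_single <- isi_ok & snr_ok
  out$qc_reason <- vapply(seq_len(nrow(units)), function(i) {
    r <- character(0)
    if (!isi_ok[i]) r <- c(r, "isi")
    if (!snr_ok[i]) r <- c(r, "snr")
    if (length(r)) paste(r, collapse = ";") else "pass"
  }, character(1))
  out
}

#' Write a per-unit QC report
#'
#' @param units Output of [qc_units()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(units, path) {
  utils::write.csv(units, path, row.names = FALSE)
  invisible(path)
}
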