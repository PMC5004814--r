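# vibrotact

Spike-train analysis of rat primary somatosensory cortex (S1) during
discrimination of whisker vibrotactile sequences.

Rats discriminating rapid trains of whisker impulses often rely on a
time-integrated feature — the mean speed of the whole train — rather than
on the kinematics of individual deflections. Whether S1 itself performs
that temporal integration is the scientific question this package's
analyses address: given trial-aligned spike trains recorded while an
animal discriminates impulse sequences, on what time scale does each
neuron encode the stimulus, and which neurons instead carry signals about
the upcoming behavioral choice?

The package implements the full analysis chain as reusable functions, and
ships a seeded synthetic-session generator so every stage is testable
without the original recordings:

* **Stimulus kinematics** — parametric raised-cosine panel pulses
  (F/M/S: 8/11/14 ms rise, ~1 mm amplitude), sequence assembly with a
  34-ms interpulse interval, mean-speed features, and the
  integrated-speed regressors.
* **Synthetic sessions** — behavioral trial tables from a logistic
  psychometric of mean panel speed, plus inhomogeneous-Poisson spike
  trains (thinning, 0.1-ms resolution) from five unit archetypes: Fast
  (velocity-scaled phasic responses with paired-pulse adaptation), Medium
  (impulse-triggered suppression), Slow Positive (weak sustained
  responses plus a choice-correlated late ramp), Slow Negative
  (within-trial rate decline), and Unmodulated.
* **Unit QC** — interspike-interval criterion (< 0.5% of intervals below
  1.5 ms), waveform SNR > 2, RS/FS split at 0.375 ms trough-to-peak
  width, laminar assignment from depth (L2/3 200–650 µm … L6 1575–2200 µm).
* **Response analysis** — 1-ms PSTHs, an exact permutation test for
  temporal modulation (10-ms bins, spike times re-drawn uniformly within
  the 0–180 ms epoch), impulse-evoked response metrics (baseline −10–0 ms,
  peak in a 40-ms window with 10-ms smoothing, mean evoked 5–35 ms),
  adaptation ratios (pulse *N*/pulse 1), choice bias (right − left rate
  5–50 ms after the final impulse), and sliding-*t* divergence times.
* **Integration windows** — for each unit, OLS of 5-ms-binned rate on
  panel speed integrated over the preceding *W* ∈ {5, 10, …, 180} ms
  (36 regressions stacked over the four sequences), Bonferroni selection
  of the best window (α = 0.05/36 = 0.0014), and classification:
  Fast (5–20 ms), Medium (25–50 ms), Slow Positive/Negative (55–180 ms by
  slope sign).
* **Population decoding** — per-unit one-vs-all ridge-logistic
  classifiers over binned single-trial counts (10-ms bins or a single
  150-ms bin over 0–150 ms), probabilities renormalized per unit and
  summed across units (equal vote mass), 70/30 stratified splits with
  5-fold cross-validated penalty selection, repeated fitting/decoding;
  rate-normalized and time-scrambled controls; a binary choice decoder
  evaluated per stimulus on choice-balanced held-out sets.
* **Behavior** — per-stimulus choice fractions, bias-corrected relative
  right choice, d′ = z(hit) − z(fa) with 1/(2n) clipping, the two-sample
  proportion test for FMS vs SMF (Bonferroni threshold 0.00625), and the
  fixed-panel comparison measure.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints its findings and writes tables under `results/`:

```sh
Rscript analysis/01_simulate_session.R   # default synthetic session
Rscript analysis/02_behavior.R
Rscript analysis/03_qc_modulation.R
Rscript analysis/04_response_metrics.R
Rscript analysis/05_integration_windows.R
Rscript analysis/06_decoding.R
```

Stage 2 shows the behavioral signature of integration — choice tracks
mean sequence speed, so FFF and SSS separate (d′ = 2.32) while FMS and
SMF, matched in mean speed, do not (proportion test p = 0.102, threshold
0.00625):

```
 stimulus  n mean_speed_mm_s fraction_right relative_right
      FFF 50           53.10           0.92          0.345
      FMS 50           49.46           0.52         -0.055
      SMF 50           49.46           0.68          0.105
      SSS 50           44.95           0.18         -0.395
```

Stage 5 recovers the generating archetypes from spikes alone (96.4%
class recovery on the default session; every Fast unit lands at a 5-ms
best window), and stage 4 recovers the imposed adaptation
(2/1: 0.82 ± 0.12, 3/1: 0.62 ± 0.10) and the Slow-Positive choice bias
(+9.8 Hz on right-choice trials, paired t p = 0.0012, baseline control
p = 0.11). Stage 6 reproduces the decoding dissociation on a pooled
population (chance 25%):

```
  Fast/Medium units, 10-ms bins:    63.1%
  Fast/Medium, single 150-ms bin:   35.5%
  Fast/Medium, rate-normalized:     65.1%
  Fast/Medium, time-scrambled:      29.6%
  Slow units, 10-ms bins:           28.4%
```

Temporal spike patterns, not overall rates, carry the stimulus: rate
normalization leaves decoding intact while time-scrambling collapses it.

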