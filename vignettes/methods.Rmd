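---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents how `vibrotact` models the whisker vibrotactile
discrimination experiment, which parameters matter and why their defaults
were chosen, what the synthetic-data generator does and does not emulate,
and the numerical decisions taken where the analysis left genuine freedom.

## Stimulus model

Each panel impulse is a ramp-return deflection parameterized by rise time,
fall time, and peak amplitude. The published kinematic tables fix those
three numbers (and a nominal peak velocity) but not the ramp profile. We
use a raised-cosine position ramp,
$x(t) = \tfrac{A}{2}\bigl(1 - \cos(\pi t / T_\mathrm{rise})\bigr)$,
because the recorded panel traces show smooth ramps with mid-ramp velocity
maxima; amplitude and rise/fall time are treated as authoritative and the
peak velocity is derived, $v_\mathrm{peak} = 1000\,A\pi/(2T)$ mm/s. For
the three-pulse set this lands within ~15% of the nominal peak
velocities (202 vs 220 mm/s for F, 164 vs 170 for M, 128 vs 110 for S);
the printed amplitude/time/velocity triple is mutually over-determined,
so no ramp shape can match all three at once.

Two further published quantities do not follow from the pulse parameters
under any return-to-zero ramp model:

* the per-sequence mean speeds, and
* the sequence durations quoted in the kinematic table.

Both are therefore treated as informational. Only orderings and
equalities are asserted: FMS and SMF are built from identical pulse sets,
so their mean speeds agree to floating point, and mean speed computed
over each sequence's *own duration* (first onset to last offset) orders
the set FFF > FMS = SMF > SSS. A fixed common window cannot produce that
ordering, because total travel is $2A$ per pulse and the amplitudes are
nearly equal — this is why the behavior generator uses own-duration mean
speed as its decision variable.

Waveforms are sampled at `dt_ms = 0.5` (the sampling step must divide the
rise/fall times); integrals use the trapezoid rule. The integrated-speed
regressor for rate bin $[t, t+5)$ is $\int_{t-W}^{t} |v|\,dt$ in mm of
travel — the raw integral, not the integral divided by $W$. $R^2$ and
the regression p-value are invariant to affine rescaling of the
regressor (a tested property), so this choice cannot affect window
selection or classification; slopes are reported in Hz per mm of
integrated travel.

## Synthetic sessions

The generator's role is to produce data with the statistical structure
the analyses assume, with known ground truth. It is not a biophysical
model, and the archetype parameterizations are this package's own
constructions, calibrated once to the qualitative response shapes that
define each class:

* **Fast** — baseline plus an alpha-kernel transient per pulse
  (latency 5 ms, width 4 ms), scaled by the pulse's analytic peak
  velocity times a per-position adaptation multiplier (default 1, 0.8,
  0.7, matching the modest adaptation of F trains). Velocity gain
  0.25 Hz/(mm/s) puts F-pulse transients near 50 Hz over a ~6 Hz
  baseline.
* **Medium** — baseline 20 Hz minus a broader suppression kernel
  (latency 12 ms, width 15 ms, depth 14 Hz). The kernel width is what
  places these units' best integration windows in the 25–50 ms band;
  narrower kernels migrate into the Fast band and wider ones into the
  Slow band, which is exactly the class-boundary structure the
  classification probes.
* **Slow Positive** — baseline plus small sustained responses to pulses
  2+ and, on right-choice trials only, a linear ramp of height 8 Hz
  beginning at the end of the second impulse and reaching plateau
  mid-third-impulse. The onset matches the observation that
  choice-divergent firing begins after the second impulse; note that
  most of the ramp's spike mass therefore falls *after* 150 ms, with
  consequences for single-window choice decoding (below).
* **Slow Negative** — linear rate decline (0.05 Hz/ms from a 15 Hz
  baseline) with no impulse coupling.
* **Unmodulated** — constant rate; these units should be flagged by the
  modulation test at only the false-positive rate and classified at only
  the family-wise rate.

Per-unit baselines are drawn from log-normal distributions centered on
the archetype baseline (sd 0.4 on the log scale), reflecting the
positively skewed firing-rate distributions of cortical recordings.
Spike trains are inhomogeneous Poisson, sampled by thinning against the
trace maximum on a 0.1-ms grid (the digitization order of magnitude of
the recordings); expected counts match the trapezoid integral of the
rate trace (tested against the sampler at 4000 repeats). Withdrawal
times are a shifted gamma (shape 2) truncated at the 150-ms task
minimum with mean 190 ms. The psychometric is a lapse-adjusted logistic
of own-duration mean speed (slope 0.45 per mm/s, midpoint halfway
between the fastest and slowest sequences, lapse 0.05); with ~4 mm/s
between FFF and the midpoint this yields ~85–90% right choices to FFF,
matching a trained animal's asymptotic performance.

What the generator does **not** emulate: correlated variability between
units, non-Poisson spiking statistics (refractoriness, bursting), drift
within sessions, whisker biomechanics, or reafference. Passing tests on
synthetic sessions therefore demonstrate that the analysis chain
recovers the structure it assumes — not that real S1 data contain that
structure.

## Statistical procedures and numerical choices

**Temporal-modulation test.** The published description fixes the
comparison (10-ms bins, 10,000 permutations of spike times) but not the
statistic or the permutation scheme. We redraw each spike's time
uniformly within the 0–180 ms epoch per trial — preserving per-trial
counts, destroying all timing — and use the sum over bins of squared
deviations of the binned rate from the epoch mean. With the add-one rule
$p = (1 + \#\{S_\mathrm{null} \ge S_\mathrm{obs}\})/(1 + N)$ the test is
exact, and its type-I error on stationary Poisson units is verified to
sit at or below 5%. The redraw is vectorized across permutations;
because the statistic depends only on pooled binned counts, this is
identical to the per-trial loop.

**Evoked metrics.** Peak modulation is the signed extremum of the
10-ms-boxcar-smoothed 1-ms PSTH within 40 ms of pulse onset, relative to
the 10-ms pre-pulse baseline. An even-width boxcar is realized as a
symmetric kernel with half-weight endpoints, so smoothing introduces no
half-bin shift; when smoothing flattens the extremum into a plateau, the
latency is reported at the plateau midpoint. Adaptation ratios exclude
units whose pulse-1 evoked rate is not positive (recorded as missing).

**Window regression.** The 36 regressions stack the four sequences'
5-ms-binned trial-averaged rates into one design (144 observations), as
a single best window per unit is reported; fitting sequences separately
is the main documented alternative. No latency offset is inserted
between regressor and rate bin. Significance uses the OLS F-test of the
slope at α = 0.05/36 ≈ 0.0014; ties in $R^2$ break toward the smaller
window; the boundary window 55 ms is assigned to the Slow class (the
published ranges touch at 55), and this boundary is configurable.

**Decoders.** Each unit is an independent classifier; the population
prediction maximizes summed per-unit probabilities, with per-unit
probabilities renormalized to sum to 1 so every unit has the same vote
mass. Logistic fits use ridge-penalized IRLS (compiled, unpenalized
intercept), with the penalty chosen by 5-fold cross-validated held-out
deviance inside the 70% training split over the grid
{0.01, 0.1, 1, 10, ∞}, where ∞ is the intercept-only null model. The
grid's null-model end matters for calibration: on stimulus-independent
units, cross-validation can select the prior, which removes most of the
overfitting tilt that otherwise inflates the variance of the chance-level
estimate. The flip side is conservatism: per-unit signals too weak for
5-fold CV to certify are shrunk to the prior, so small Slow cohorts
decode choice from the 0–150 ms bin at chance even when the
pre-withdrawal window (which contains the choice ramp's plateau) decodes
above it. Test events draw one held-out trial per unit per event,
without replacement within the queried class, decoupling units as the
independence assumption intends; argmax ties break uniformly at random
under the run seed. Choice-decoder test sets are balanced within each
stimulus so 50% remains a meaningful chance level under behavioral side
bias.

A point worth knowing when interpreting chance calibrations: the
evaluation repeats splits on a *single* generated session, so its
Monte-Carlo uncertainty is dominated by dataset-level noise (finite
trials and units), not by the number of repeats. At 100 units and 100
trials per sequence the chance-level estimate has a standard deviation
of roughly 1.5 percentage points around 25%; repeat-level standard
errors alone understate this.

**Behavior.** d′ uses the equal-variance Gaussian form with rates
clipped to $[1/(2n), 1 - 1/(2n)]$ (the published analysis does not state
a clipping rule; this is the standard correction). The proportion test
is the two-sample z-test computed directly (identical to the
continuity-uncorrected chi-squared), Bonferroni-corrected at 0.05/8.

**QC.** Laminar bins are half-open and lower-closed — the published
ranges print touching boundaries (650 µm appears in both L2/3 and L4),
so boundary depths go to the deeper layer; depths above 200 µm only,
as no units were reported more superficially. ISI and SNR thresholds
are applied as strict inequalities exactly as printed.

## Problem sizes

Defaults are study-scale where the analyses need them (10,000
permutations, 300 decoder repeats). The shipped test suite and the
calibration script use sizes chosen to make Monte-Carlo error small
relative to the assertion bands while keeping runs short: sessions of
28–100 units, 2000 permutations for the modulation screen (type-I error
is unaffected by permutation count beyond resolution), 100 decoder
repeats for calibration, and 8–50 repeats for direction-of-effect
checks. The analysis drivers in `analysis/` state their sizes inline.

## Known limitations

* The classification's Medium band (25–50 ms) sits between two
  boundaries, and suppression-type units near either edge genuinely
  straddle classes; the default generator places ~90% of Medium units
  inside the band, and that recovery rate is pinned as the package's
  regression baseline rather than a claim about real cortex.
* The sliding-t divergence time requires several units to have power;
  single-session Slow cohorts (3–5 units) yield late or absent
  divergences even when the generating ramp is present.
* Real-data accuracies (e.g., the published decoder performance) are out
  of scope without the deposited recordings; all quantitative assertions
  here are about calibration and recovery on synthetic data.
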