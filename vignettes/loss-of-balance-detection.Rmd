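---
title: "Detecting loss of balance from joint EEG/EMG analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting loss of balance from joint EEG/EMG analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobdetect)
library(dplyr)
```

## The problem and the model

A near fall is a loss of balance recovered without ground impact — most
often a slip, trip or misstep. Detecting one *before* any impact, and doing
so without flagging ordinary activities of daily life (ADL: steady walking,
tight curves, chair transfers, obstacle avoidance), is what makes a
detector usable outside the lab: countermeasures such as exoskeleton
assistance must engage within roughly half a second of the perturbation,
and false alarms at the rate ordinary movement occurs would make any such
system intolerable.

`lobdetect` implements a rule-based detector that fuses two
electrophysiological signatures of a reactive balance response:

* **Muscular**: support-surface perturbations evoke a short-latency
  (70–300 ms) response in the ankle muscles with agonist–antagonist
  co-contraction — a muscular pattern that differs from the stereotyped,
  phase-locked pattern of steady gait.
* **Cortical**: a reactive response involves a *widespread*, bilateral
  increase in EEG band power (θ 4–7, α 8–12, βI 13–15, βII 16–20,
  βIII 21–40 Hz), whereas routine asymmetric movements (turning, stepping
  over an obstacle) produce more *lateralized* modulations.

The processing chain, per contraction:

1. **ON/OFF muscular patterns (OOM).** Each of 10 lower-limb EMG channels
   (anterior tibialis, lateral gastrocnemius, vastus medialis, rectus
   femoris, biceps femoris, both legs; 500 Hz) is binarized by a moving
   power threshold: the mean square of the last $N = 125$ samples
   ($P_N$, instantaneous power) against the mean square of the last
   $M = 250$ samples ($P_M$, adaptive threshold); the muscle is ON iff
   $P_N > P_M$ (strictly). The relative comparison tracks slow tone
   changes (fatigue) with no absolute amplitude calibration.
2. **Master trigger (MT).** A rising edge of either lateral gastrocnemius
   OOM anchors all feature extraction. The gastrocnemius is chosen because
   it activates specifically at midstance, so the trigger time-locks the
   analysis to a known gait phase. Edges within a 300 ms refractory of the
   last accepted trigger are ignored; an exact left/right tie resolves to
   the right.
3. **Muscular activity pattern (MAP) and score.** In an 11-sample window
   centered on the MT edge (10 ms either side at 500 Hz), each muscle
   enters the pattern iff it is ON for strictly more than half the window.
   The pattern is scored against per-leg occurrence weights
   $\mathrm{MS} = \sum_i \mathrm{MAP}(i) W(i) / \sum_i W(i)$ — near 1 for
   the subject's standard step, low when the normally active muscles are
   silent. Weights are learned from non-flagged contractions only, so
   perturbations never contaminate the "standard" pattern; separate
   right-leg and left-leg vectors absorb gait asymmetry.
4. **Cortical slopes.** The 400 EEG samples (800 ms) preceding the trigger,
   from 13 scalp sites (F3 Fz F4 / C3 Cz C4 / Cp5 Cp1 Cp2 Cp6 / P3 Pz P4),
   pass a pluggable artifact-attenuation step (identity by default), then a
   sliding FFT: 20 windows of 200 samples at a 10-sample hop (2.5 Hz
   resolution). Bin powers are floored, converted to dB and summed per
   band; an ordinary-least-squares line over the 20 window times
   (20–400 ms) gives a slope $\hat m$ (dB/ms) per channel and band — the
   rate of power build-up before the contraction.
5. **Generalization and lateralization.** Channel slopes are summed into 4
   functional groups (SMA: F3 Fz F4; M1: C3 Cz C4; S1: Cp5 Cp1 Cp2 Cp6;
   PPC: P3 Pz P4) per band (20 values), and into per-band left/right
   hemisphere ratios (left = F3 + C3 + P3 + mean(Cp1, Cp5), right
   analogous; 5 values). Both hemisphere sums are rectified at a small
   floor before the ratio, because a ratio of power *increments* is
   meaningless when either side shows none.
6. **Adaptive thresholds and the three-level logic network.** A
   calibration block (default 20 contractions of unperturbed movement)
   seeds a lower threshold on the muscular score (5th percentile − margin)
   and upper thresholds on the 20 group slopes (95th percentile). From
   then on thresholds track the rolling median over 15 contractions but
   move only toward the "worst" value (score threshold down, slope
   thresholds up), so an activity block that legitimately lowers scores
   (obstacle avoidance) widens the operating range permanently instead of
   oscillating. Per contraction:
   * level 1: a band's generalization flag fires iff **more than 2** of
     the 4 groups exceed their slope thresholds; F1 fires iff more than 2
     of the 5 bands flag — a widespread, multi-band build-up;
   * level 2: a band's lateralization flag fires iff its ratio leaves
     $[1-\varepsilon,\, 1+\varepsilon]$; F2 fires iff **fewer than 2**
     flags are active — the build-up is not lateralized;
   * level 3: loss of balance iff $F1 \wedge F2 \wedge \mathrm{MA}$, where
     the muscular alert MA fires iff the score is strictly below its
     threshold.

All comparisons are strict, so ties (a score exactly at threshold, a ratio
exactly at $1+\varepsilon$) never alert — degenerate inputs have a
deterministic, conservative outcome.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `M`, `N` | 250, 125 samples | moving-threshold and instantaneous power windows (500, 250 ms) |
| `refractory_ms` | 300 | minimum spacing of master triggers; prevents re-triggering within one gastrocnemius burst |
| `power_floor` | 1e-12 | absolute mean-square floor under which a sample is never ON; guards the scale-free comparison against float residue in silent stretches (hardware front-ends have a 16-bit quantization floor) |
| `Lw` | 11 samples | pattern window around the trigger edge |
| `pretrigger_samples` | 400 | EEG history analyzed per contraction |
| `L_win`, `step`, `nW` | 200, 10, 20 | sliding-FFT geometry; 2.5 Hz bins, fit abscissa 20–400 ms |
| `epsilon` | 0.5 | lateralization tolerance (below) |
| `window_len` | 15 | rolling threshold window, contractions |
| `calibration_contractions` | 20 | contractions consumed before decisions are emitted |
| `adapt_margin` | 0.1 | score-units margin below the threshold statistic |
| `weight_mode`, `weight_lambda` | exponential, 1/15 | streaming weight update (geometric forgetting) |

Two defaults deserve their rationale spelled out.

**The lateralization tolerance `epsilon = 0.5`.** The per-band ratio divides
two hemisphere slope sums. Even for a strong, perfectly symmetric power
ramp, those sums carry multiplicative dispersion of a few tens of percent:
the periodogram of any stochastic signal has bin-level dB variance that no
amplitude can reduce, and amplitude modulation within an FFT window leaks
phase-dependent sidebands into neighboring 2.5 Hz bins. Measured on the
synthetic sessions, symmetric slip responses produce ratios in roughly
[0.7, 1.4], while genuinely lateralized responses push the ratio beyond 2
(or collapse it onto the rectification floor, giving extreme values). A
tolerance of 0.1 would therefore reject essentially every true symmetric
response at level 2; 0.5 separates the two regimes cleanly. The parameter
remains config-exposed for other signal regimes.

**The muscular margin `adapt_margin = 0.1`.** The seeding quantile of a
*degenerate* calibration distribution — every standard step scoring exactly
1, which is the typical case when the standard pattern is stable — collapses
onto 1 itself, and the strict `<` comparison would then flag any score
below 1, however marginal. The margin keeps the threshold a tenth of the
score range below the calibration statistic. The cortical thresholds use a
separate margin (default 0) because their seeding quantile comes from a
continuous distribution and is already an upper bound.

## Numerical choices

* **Zero-phase vs causal filtering.** EEG is filtered zero-phase
  (forward–backward 8th-order Butterworth 1–40 Hz plus a 4th-order
  48–52 Hz band-stop): offline, this avoids group-delay skew of the
  pre-trigger window. The EMG chain (15–250 Hz band-pass, upper edge
  clipped below Nyquist at 500 Hz, plus the notch) runs *causally* by
  default: a zero-phase IIR pre-rings at roughly 1% amplitude ahead of
  each burst, and because the ON/OFF rule is a relative power comparison
  it latches onto that anticipatory energy and fires activations ~200 ms
  before the physical contraction. The physical acquisition node filters
  causally anyway. Both choices are config flags.
* **Resampling.** 2048→500 Hz is a non-integer factor (4.096). The
  resampler applies a zero-phase Butterworth anti-alias low-pass at
  0.45 × 500 Hz and evaluates the band-limited signal at the exact 500 Hz
  instants by cubic spline, preserving duration within one sample with no
  phase lag.
* **Band→bin mapping.** A 2.5 Hz bin belongs to a band iff its center lies
  within the band's Hz range widened by half a bin (±1.25 Hz):
  θ → {5, 7.5}, α → {7.5, 10, 12.5}, βI → {12.5, 15}, βII → {15, 17.5,
  20}, βIII → {20 … 40}. This covers 4–40 Hz without gaps, keeps at least
  two bins per band, and is overridable with explicit bin lists.
* **dB before summation.** Band values are sums of per-bin dB powers
  (floored at `db_floor` so silent bins stay finite); summing raw power
  first and converting once is available via `db_sum = FALSE`.
* **Spectral normalization.** One-sided bin powers are scaled so they sum
  to the segment's mean square (Parseval), making the energy bookkeeping
  testable to machine precision.
* **OLS.** Slopes use the closed-form centered estimator; it matches a
  generic least-squares solve to 1e-9 and is exercised for unbiasedness by
  simulation.

## What the synthetic generator emulates — and what it does not

`scenario_spec()` + `generate_session()` render seeded, annotated sessions
with the statistical structure the detector assumes:

* **EMG**: per-muscle Gaussian-envelope bursts of white noise locked to
  gait phase at 0.9 cycles/s (legs antiphase), with N(0, 20 ms) timing
  jitter. The lateral gastrocnemius fires at midstance so master triggers
  arise naturally; the contralateral anterior tibialis and biceps femoris
  lead it by ~80 ms and the stance leg's loading-response vasti tails
  overlap it, forming a stable five-muscle standard pattern for the
  weights to learn. Burst phases are chosen so no other activation tail
  straddles a gastrocnemius edge, keeping pattern membership stable.
* **EEG**: stationary narrowband rhythms at every 2.5 Hz analysis bin from
  5 to 40 Hz, amplitudes ∝ f^-0.5 (so power keeps the 1/f profile of
  resting EEG), over a weak pink-noise floor, with per-channel random
  phases.
* **Slips**: a multiplicative amplitude ramp (default ×4) on *all* EEG
  channels across the ~800 ms leading into the first gastrocnemius edge
  after the perturbation onset, plus a muscular anomaly: the standard
  companion bursts are suppressed and a delayed agonist–antagonist
  co-contraction (ankle-strategy latency) follows the trigger. The slip
  score therefore drops to ~0.2 while the cortical build-up is widespread
  and symmetric.
* **ADL events** (curves, chair transfers, obstacle): the same ramp
  (default ×2) applied to one hemisphere only, with the muscular pattern
  left intact — lateralized cortical response, standard score.

The default amplitudes are fixed once so that the default scenarios sit
clearly on the correct side of the decision rules; `noise_amp`,
`baseline_noise` and the gains are the knobs for studying degradation.

What this does **not** model — and hence what passing tests do *not* show
about real recordings: EMG baseline noise (the default is silent between
bursts, because the relative ON/OFF rule flickers on *any* stationary
baseline, at any amplitude — a real deployment relies on the front-end's
quantization floor and on the muscles' burst-like activity); nonstationary
band power (real EEG rhythms wax and wane, so real thresholds need wider
margins than the synthetic calibration suggests); movement and ocular
artifacts (the attenuation interface is identity by default; a winsorizing
cleaner and a plug-in hook are provided, but no subspace reconstruction is
re-implemented); volume conduction, electrode impedance drift, and any
biomechanical coupling between the perturbation and the EEG.

## Evaluation harness

`match_events()` pairs truth slips with detections greedily (earliest
detection within 1 s; the reference worst-case latency is 634 ms, so the
window must exceed it), counting unmatched detections as false alarms.
`sensitivity()`, `specificity()`, `aggregate_metrics()` (mean ± n−1 SD,
two decimals) and `detection_time_stats()` reproduce the standard report
arithmetic; `metrics_from_counts()` applies them to a counts table. The
shipped `inst/extdata/*_validation_counts.tsv` files carry the reference
detection counts (and the reported per-subject percentage columns) used by
the metric-arithmetic checks; the reported obstacle-avoidance column is
aggregated from the per-subject values because its subject-1 entry does not
recompute from its own task counts.

## Worked example

```{r example, eval = FALSE}
events <- tibble::tibble(onset_s = seq(25, 61, by = 4), label = "slip",
                         side = rep(c("R", "L"), 5), duration_s = 0.8)
spec <- scenario_spec(duration_s = 70, events = events, seed = 1)
session <- generate_session(spec)

det <- run_detect(session$eeg, session$emg)
glance(det)
evaluate_session(det, session$truth)
plot_feature_plane(det)
```

On this session the detector calibrates on the first 20 contractions,
monitors about 100 more, recovers 10/10 injected slips with mean latency
near 320 ms, and flags one walking contraction adjacent to a slip (the
cortical ramp of the impending slip already overlaps that step's analysis
window).

Problem sizes used throughout the test-suite and the acceptance script —
70 s sessions, 10 slips and ~100 monitored contractions per session, ten
seeds per condition, 1000 Monte-Carlo replicates for the slope-bias check —
were chosen as the smallest sizes at which the binomial rates of interest
(≥90% sensitivity, <5% false alarms) are measured on ≥100 events each.

## Known limitations

* The detector is a per-subject, auto-adaptive rule system; nothing is
  learned across subjects, and no claim is made that the synthetic
  operating point transfers to clinical populations.
* Monotone (worst-ward) threshold adaptation never recovers when an
  activity block legitimately ends; the reference behavior is reproduced
  deliberately, and `adapt_thresholds(reset = TRUE)` is the escape hatch.
* The lateralization statistic is fragile near zero slopes by
  construction; the rectification floor makes it exactly 1 when both
  hemispheres show no increase, which silently disables level 2 for
  low-power contractions.
* EDF support covers the 16-bit single-rate subset sufficient for this
  pipeline, not the full standard.
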