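# lobdetect

Rule-based detection of loss-of-balance (near-fall) events from
synchronized EEG and lower-limb EMG, for researchers in neuromotor signal
processing and pre-impact fall detection who need a tested, reproducible
reference implementation of a threshold-logic detector — plus a seeded
synthetic generator of gait-locked EEG/EMG sessions to exercise it.

## The method

Ten EMG channels (AT, LG, VM, RF, BF muscles × both legs, 500 Hz) are
binarized into ON/OFF activation patterns by a moving power threshold: a
sample is ON iff the mean square of the last N = 125 samples exceeds that
of the last M = 250 samples (strictly),

    OOM(t) = 1  iff  P_N(t) > P_M(t).

Rising edges of either lateral gastrocnemius pattern are **master
triggers** (midstance-specific). At each trigger, an 11-sample window
marks which muscles are ON for more than half the time (the muscular
activity pattern, MAP), scored against learned per-leg occurrence weights

    MS = Σ_i MAP(i) · W(i) / Σ_i W(i)  ∈ [0, 1],

near 1 for the subject's standard step, low for co-contraction anomalies.
In parallel, the 400 EEG samples (800 ms) preceding the trigger from 13
scalp sites are reduced by a sliding FFT (20 × 200-sample windows, hop 10,
2.5 Hz bins) to per-band dB power trajectories, and an OLS line over the
20 window times gives a slope m̂ (dB/ms) per channel and band
(θ, α, βI, βII, βIII). Slopes aggregate into 4 functional groups
(SMA, M1, S1, PPC) per band and into per-band left/right ratios.

A three-level logic network with self-calibrating thresholds decides:
F1 = more than 2 bands have more than 2 groups above their slope
thresholds (widespread build-up); F2 = fewer than 2 bands have a
lateralized ratio (|ratio − 1| > ε); MA = muscular score below its
threshold. A contraction is a **loss of balance** iff F1 ∧ F2 ∧ MA;
otherwise it is an activity of daily life (ADL), and it updates the
weights and the rolling (median-based, monotone) thresholds.

## Worked example

Simulate a 70 s walking session with ten slips, run the detector, and
score it against the generated ground truth:

```r
library(lobdetect)

events <- tibble::tibble(onset_s = seq(25, 61, by = 4), label = "slip",
                         side = rep(c("R", "L"), 5), duration_s = 0.8)
spec <- scenario_spec(duration_s = 70, events = events, seed = 1)
session <- generate_session(spec)

det <- run_detect(session$eeg, session$emg)
det
#> <lob_detection> 124 contractions (20 calibration, 104 monitored); 11 loss-of-balance decision(s)

evaluate_session(det, session$truth)
#> # A tibble: 1 × 10
#>   n_slips n_detected n_adl n_false_alarms se_pct sp_pct dt_mean_ms ...
#> 1      10         10    94              1    100   98.9        325
```

All ten injected slips are recovered (`se_pct = 100`) with a mean
detection latency of 325 ms from perturbation onset — inside the ~550 ms
window in which a balance-restoring countermeasure can still act. One of
the 94 daily-life contractions is flagged (`sp_pct = 98.9`): the walking
step immediately preceding a slip, whose analysis window already overlaps
the slip's cortical ramp. `plot_feature_plane(det)` shows each contraction
in the (muscular score, SMA α-slope) plane with the operating thresholds;
`tidy(det)`, `glance(det)` and `tidy(det$thresholds)` give tabular views.

The evaluation verbs also reproduce standard report arithmetic directly:

```r
aggregate_metrics(c(90, 100, 90, 90, 90, 100))
#> # A tibble: 1 × 3
#>    mean    sd     n
#> 1  93.3  5.16     6
```

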