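---
title: "Ensemble-averaging imputation of posture time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-averaging imputation of posture time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimpute)
```

## The model

### Posture from the trunk angle

A single chest-worn tri-axial accelerometer measures, at rest, the
gravity vector in the sensor frame. The trunk declination angle in the
sagittal plane is

$$\theta(t) = \pm\frac{180}{\pi}\arccos\!\left(\frac{a_z(t)}{\lVert a(t)\rVert}\right),$$

with the sign taken from $a_y$: positive when $a_y \ge 0$, negative
otherwise. The classification is deliberately coarse — three states are
enough for 24-h behaviour profiles and are robust to sensor placement:

* **reclining** — $\theta$ outside the upright band, merging supine,
  prone, and side-lying;
* **sitting_or_standing** — $\theta$ inside the band
  $[\theta_\mathrm{lo}, \theta_\mathrm{hi}]$;
* **walking** — upright *and* the step detector fires.

The band edges default to 35° and 143°. They sit at the valleys of the
occurrence histogram of $\theta$ over a long recording: upright time
piles up near 90°, reclining time near the horizontal orientations, and
the sparsely visited angles between them are where a threshold misclassifies
least. `estimate_thresholds()` finds these valleys on a smoothed
histogram; the defaults suit elderly inpatients (whose kyphosis and
sloped hospital beds shift the reclining mode), while per-session
estimation is available when that assumption is doubtful.

The sign convention — mapping negative (prone-side) angles to reclining —
is a design choice: the three-state scheme does not distinguish prone
from supine, so the whole complement of the upright band is reclining.
Walking detected while the trunk is outside the upright band is ignored
as a false positive of the step detector (shuffling in bed, transfers).

### The step detector

The walking overlay uses a rules-based peak detector on the acceleration
norm: subtract a 1-s moving-average baseline, find local maxima above
`peak_threshold` (0.1 g), and accept maximal runs of peaks whose
successive intervals all lie in `[min_interval, max_interval]`
(0.3–2.0 s, the human cadence range) with at least
`min_consecutive_steps` (4) peaks. The run's full span is marked walking.
These constants are this package's own calibration of a generic
step-detection scheme; they are exposed in `walking_rule()` and in the
CLI config because device placement and gait pathology shift them.

### Epoch aggregation

Sample labels aggregate to a fixed time-of-day grid (`epoch_grid()`,
default 60-s epochs anchored at local midnight, half-open intervals) by
plurality, with ties broken toward the more specific activity
(walking > sitting_or_standing > reclining) so that brief, easily
outvoted walking is not erased by a split epoch. An epoch with fewer
than `min_fraction` (default 0.5) of its expected
`nominal_rate × epoch_length` samples — or with no valid samples — is
`missing`. The 0.5 default asks an epoch to be at least half observed;
sub-epoch partial losses are not otherwise modelled.

### Ensemble averaging

For a session of $N$ days, at each time of day $t$ let $N(t)$ be the
number of days with a valid label and $N_i(t)$ how many of those show
posture $i$. With posture sampling rate $f$ (epochs per minute), the
ensemble-averaged period of posture $i$ is

$$P_i(t) = \frac{N_i(t)}{f\,N(t)},$$

a fractional period in minutes with $\sum_i P_i(t) = f^{-1}$ wherever
$N(t)\ge 1$. With a single valid day the day's label passes through
unchanged; the epoch is undefined only when **all** days lost it. Daily
totals are $T_i = \sum_t P_i(t)$ over defined epochs, and posture ratios
are taken over the measured total $\sum_i T_i$ — missing time is
excluded, not redistributed, so ratios compare sessions with different
completeness fairly.

The key statistical assumption is *day-to-day stationarity of the daily
routine*: ensemble averaging treats the measurement days as exchangeable
draws of the same 24-h behaviour pattern. It is appropriate for settings
with a stable schedule (a rehabilitation ward; habitual free-living
weeks) and over short sessions during which the subject's condition does
not change; it is *not* appropriate across a weekday/weekend boundary or
a rapid recovery phase.

The ensemble keeps fractional $P_i$ rather than forcing a label per
epoch; `hard_labels()` (plurality of day counts, same specificity
tie-break) exists for export and plotting only, because collapsing
discards exactly the graded information the averaging gains.

### Baseline and metrics

The conventional baseline keeps the measurement day with the fewest
missing epochs (ties to the earliest day). The missing rate of a series
is the percentage of the 1440-epoch grid that is missing; for a raw
multi-day session the reference "no imputation" rate is the *mean* of
the per-day rates — the neutral mapping of a 48-h recording onto a 24-h
rate, chosen here as a design decision since max or pooled fractions are
equally defensible. By construction the ordering

$$\text{ensemble} \le \min_d \text{day}_d \le \text{conventional} \le \text{reference}$$

holds on every session, not just on average; the test suite asserts it
property-style.

## The validation harness

`inject_losses()` masks
$\lfloor \text{rate}\times E/\ell\rfloor$ non-overlapping blocks of
$\ell$ epochs placed uniformly at random (rejection over uniform starts),
a missing-completely-at-random model of the block losses that wireless
drop-outs produce. Placement is exact in count, never unmasks data, and
is deterministic given the seed. Time-of-day-correlated (MNAR) dropout
is deliberately not the default: the method's known failure mode is loss
recurring at the same clock time on all days, and the harness should
measure the MCAR regime the method targets.

`run_imputation_comparison()` scores the three methods per session and
summarises medians/quartiles within missing-rate groups whose edges
default to the quartiles of the observed reference rates (they are
percentile analogs computed from the input, not fixed constants).
Significance testing is left to the caller — the harness emits the
per-group arrays, and standard `kruskal.test`-style workflows apply
directly.

`run_ratio_stability()` starts from near-complete sessions (under 1%
native missing, mirroring recordings of over 23 h per day), sweeps
injected loss rates, and records per-posture totals and ratios across
replicate loss draws. Under MCAR losses the *ratios* should be nearly
invariant even as the measured total shrinks; the acceptance suite
checks that at loss rates up to 25 % the reclining and upright ratio
medians over 50 replicate draws stay within one percentage point of the
no-loss values, and that a 6 % per-day loss on 2-day sessions leaves a
median residual missing rate below 1 % (with independent day losses the
expected residual is about the squared rate).

## The synthetic generator

`simulate_posture_days()` draws label days from a time-inhomogeneous
Markov chain: the day is tiled by blocks with posture distributions
(defaults: reclining-dominant 21:00–06:00 nights, upright peaks around
the 08:00/12:00/18:00 meals, walking ~1 % of daytime epochs) and the
chain keeps the previous label with probability `persistence` (0.95 at
1-min epochs, i.e. ~20-min mean bouts). `render_acceleration()` inverts
the classifier: per epoch it draws a base angle from the label's regime
(reclining 10° or, with probability `supine_fraction`, 170°; upright
90°; jitter s.d. 8°), emits the gravity vector at that inclination with
0.03 g per-axis noise at 25 Hz, and modulates walking epochs with a
sinusoidal norm oscillation (0.3 g at 1.8 Hz — inside the detector's
cadence band). These defaults were chosen once so that the regimes are
cleanly separated by the default thresholds and are what the
closed-loop tests run under.

What the generator does **not** emulate: postural transitions inside an
epoch, sloped-bed intermediate angles, pathological or asymmetric gait,
sensor re-mounting shifts, and any correlation between data loss and
behaviour. Passing closed-loop tests therefore demonstrates internal
consistency of classifier, generator and ensemble — not field accuracy
on real patients, which requires labelled recordings.

## Numerical choices

* Histogram bins are half-open over $[-180°, 180°]$ with $+180°$ folded
  into the last bin, so counts always sum to the number of angles.
* Histogram smoothing is a centered moving average (default 5 bins; the
  window is forced odd) with edge-value padding, avoiding undefined
  borders.
* Valley ties resolve to the lowest angle; a flat search range yields
  the range midpoint with a warning rather than an arbitrary bin.
* `arccos` arguments are clamped to $[-1, 1]$ against floating-point
  spill; zero-norm samples are an error by default (`zero = "na"`
  converts them to invalid samples instead, which `classify_day()`
  uses).
* Seeds: every stochastic function takes an explicit seed and restores
  the caller's RNG state; replicate experiments derive child seeds
  arithmetically (kept below $2^{31}$) so runs are reproducible
  bit-for-bit.
* Problem sizes in the shipped validation: 50 sessions × 2 days × 1440
  epochs for the residual-missing-rate experiment; 1 session with 50
  replicate draws at rates {5, 15, 25} % for ratio stability; full
  25 Hz days for closed-loop classification; 4 days of 10-s epochs at
  15° jitter for threshold-valley recovery, where the reference valley
  is the numeric minimum of the configured mixture density. These sizes
  were chosen to make sampling error a small fraction of each tolerance.

## Limitations

* Losses recurring at the same clock time every day cannot be imputed;
  the residual missing set is exactly the intersection of the daily
  missing sets.
* Sessions with high overall loss (beyond roughly half the recording)
  leave the ensemble dominated by single-day epochs and shrink measured
  totals; the ratio-stability experiment quantifies the onset.
* The trunk-angle scheme cannot separate sitting from standing, nor
  detect non-ambulatory activity; `walking` depends on the step
  detector's calibration.
* Ensemble averages are *typical-day* summaries: irregular events are
  averaged away by design, which is a feature for routine profiling and
  a caveat for event detection (e.g. falls).
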