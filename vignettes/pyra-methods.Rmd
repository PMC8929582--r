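---
title: "Paired year ratio assessment: model, assumptions and design choices"
author: "pyra authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired year ratio assessment: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyra)
```

## The estimator

Detection series from fixed acoustic monitors mix three sources of
structure: a long-term trend (the quantity of interest), strong seasonal
and diel patterns of habitat use, and gaps wherever the logger was not
deployed or not running.  Paired year ratio assessment sidesteps the
seasonal nuisance entirely by comparing each day only with the *same
day-of-cycle position one cycle later*, and only when both days were fully
logged.  For paired values $y^*_k$ (year 1) and $y^*_{k+C}$ (year 2), the
summary statistic over the whole monitored span is the ratio of paired
sums

$$\hat P_T = \frac{\sum_k y^*_{k+C}}{\sum_k y^*_k},$$

pooled over all successive cycle pairs and, for regional analyses, over
all sites (summing detections first, then taking one ratio — so sites
contribute in proportion to their detections).  The windowed trend series
applies the same ratio to a forward window of span $I$ (by default one
full cycle $C$) stepped one unit at a time, and reports each ratio at the
window midpoint, $k + \lfloor C/2 \rfloor$.  Within a window the ratio of
forward moving means is computed as a ratio of sums over the *identical*
pair set: numerator and denominator always contain the same day positions,
so missing days can never unbalance the two years of a comparison.

The method's assumptions are correspondingly few: the cycle length is
known and stable (365 days here; 12 for monthly series); the
detection-to-abundance relationship, whatever it is, is stable across the
two years being compared; and within a pair, a day's position in the cycle
captures the seasonal state well enough that differencing years at fixed
positions cancels seasonality.  No distributional form is assumed.  As a
ratio estimator $\hat P_T$ is increasingly unstable as year-1 counts
approach zero, which drives several of the defaults below.

## Tunable parameters

* **`C`** (cycle length, default 365 days).  Cycles are anchored at the
  first record of each site, not at 1 January: deployments start mid-year,
  and pairing only needs *relative* positions one cycle apart.  Leap days
  are removed before indexing so that the same calendar month-day occupies
  the same day-of-cycle in every year.
* **`full_log_threshold`** (default 1).  Only whole days of logging enter
  the analysis; the threshold exists because some sensor clocks log
  1439/1440 minutes of a day that is operationally complete.  How partial
  days were identified in any given dataset is the user's call — the
  threshold is exposed rather than guessed.
* **`I`** (trend-window span, default `C`).  One full cycle is the natural
  span: every seasonal state appears exactly once in numerator and
  denominator.
* **`min_pairs`** (default 30).  Windows holding fewer pairs — about 8% of
  an annual window — are reported missing rather than risk a ratio built
  on a handful of days.  The cutoff is a stability guard, not a tuned
  constant.
* **`zero_denominator`** (default `"missing"`).  A window with no year-1
  detections has no defined ratio.  The alternative `"epsilon"` policy
  computes $(y_2 + \varepsilon)/(y_1 + \varepsilon)$ with
  $\varepsilon = 1$ by default, the same device as the $\log(1+x)$
  transform; it is opt-in because it shrinks genuine extreme ratios.
* **`w`** (bootstrap block span, default 21 pairs for daily data, about 3
  for monthly).  Blocks must be long enough that their endpoints are
  nearly uncorrelated; three weeks comfortably exceeds the day-to-day
  correlation scale of most detection series.  This is a scientific
  judgement the code documents but cannot enforce.
* **`B`** (default 1000 resamples; permutation tests default to 5000) and
  **`conf_level`** (default 0.95).

## Uncertainty: the moving block bootstrap

Resampling operates on the `(y1, y2)` pairs jointly — resampling the two
years independently would destroy exactly the pairing the estimator relies
on.  A resample draws $\lceil K/w \rceil$ blocks of $w$ consecutive pairs
uniformly with replacement from the $K - w + 1$ overlapping blocks,
concatenates them in draw order and truncates to $K$: the standard
overlapping-block reconstruction.  The phrase "a window centred at the
midpoint which slides along the series" admits more than one
reconstruction rule; the overlapping-block scheme is the textbook one and
is used throughout, which is a documented choice rather than the only
reading.  Percentile intervals use the empirical $\alpha/2$ and
$1-\alpha/2$ quantiles (R's default type-7 quantile); resamples whose
statistic is undefined under the `"missing"` policy are dropped and
counted in a diagnostics field.  For per-window bands of the trend series,
resampling is restricted to each window's own pairs.

Two properties are worth stating plainly.  With noise-free no-trend data
every resample has ratio exactly 1, so the interval collapses to width
zero.  And with only $\lceil K/w \rceil \approx 10$ blocks per resample at
the default scenario size, the percentile interval is approximate: the
test suite checks its coverage of the no-trend value over 200 simulated
data sets against a deliberately generous band (88–99%) rather than
pretending block bootstraps achieve exact nominal coverage at this sample
size.

## Randomisation trend tests

All four tests permute the observed values over the observation slots
(`B` permutations, default 5000) and use the add-one estimate
$p = (1 + \#\{\text{at least as extreme}\})/(B + 1)$, so $p$ is never 0.
Default tails follow each statistic's directional logic: two-sided on the
absolute slope for RT1, lower for the two runs statistics (trends produce
*few* runs), two-sided for the positive-differences count.  All tails can
be overridden.

For the two-sided discrete statistics the implementation uses tail
doubling, $p = \min(1,\, 2\min(p_{lower}, p_{upper}))$, rather than
distance from the *estimated* permutation mean.  With an integer statistic
whose null distribution is symmetric about a half-integer, the estimated
centre sits within Monte-Carlo error of the symmetry point and ties at
equal distance flip sides on noise, making the p-value unstable by the
size of a probability mass point; tail doubling is the standard stable
equivalent.

Tie handling follows runs-test convention: values equal to the median are
removed before counting median runs, and zero differences are removed
before counting up/down runs.

A known property of permutation tests with discrete statistics is
conservatism: the attainable significance levels step by the size of the
null mass points, so the true size at nominal 5% sits below 0.05.  The
test suite's type-I calibration therefore uses series of length 1460 — the
full 4-cycle daily span, i.e. the no-trend scenario with its seasonality
switched off — where the null distributions are dense enough that each
test's attainable size lies close to nominal (exact computations from the
runs distribution, Eulerian numbers and the up/down-runs recurrence give
0.045–0.050 at this length), with 1000 replicate series and 999
permutations each.

## The scenario generators

Two deliberately extreme cases, each 4 cycles of 365 days with Normal
daily noise (negative draws truncated at zero — detection counts are
non-negative; the truncation is essentially inactive at the default noise
levels):

* **S1, seasonal without trend**: the daily mean ramps linearly within
  each cycle from `start_mean` (default 100) to `end_mean_within_cycle`
  (default 50) and resets — identical cycles, so any estimated cross-year
  change is an artefact.
* **S2, uniform decline**: the mean falls linearly from `start_mean` on
  day 1 to `start_mean × (1 − total_decline_fraction)` on the last day
  (default decline 0.75 over the span), with no seasonal component.

The gap design retains a 100-day window per cycle that shifts forward 30
days each cycle, starting at day 1 of cycle 1 (the combinatorial counts —
`window_length × n_cycles` retained days, `window_length − window_shift`
paired positions per cycle pair — are invariant to the start day).  The
drifting window is the interesting part: it correlates the gap pattern
with the seasonal phase, which fabricates an apparent decline in S1 that
position-matched pairing must (and does) resist.

The named noise levels are calibrated to the year-start mean: 1%, 2% and
4% of `start_mean` for low/moderate/high.  The scenarios are defined by a
signal that clearly dominates daily noise — under S2's decline the paired
year-clusters must separate cleanly, which requires the daily standard
deviation to stay below a few percent of the starting level; at the
"high" setting that separation already begins to fail, which is the point
of having a high setting.  All magnitudes are plain config fields, and
every validation that depends on them either uses parameter-invariant
combinatorics or states its magnitudes explicitly.

What the generators do *not* emulate: overdispersed or zero-inflated daily
counts, serial correlation in the noise, diel structure, multi-site
heterogeneity, or detector efficiency drift.  Passing tests on these
scenarios therefore demonstrate correctness of the machinery and
robustness to seasonally confounded gaps — not performance on every real
detection series.  Real porpoise data, for instance, are both noisier and
autocorrelated; the block bootstrap exists precisely because independence
is not assumed, but its block span must then be chosen against the data's
actual correlation scale.

## Numerical and degenerate-input choices

* Midpoint plotting uses $\lfloor C/2 \rfloor$ on the integer time grid;
  plots label time in fractional cycles.
* The percent-change reading of $\hat P_T$ is reported two ways, because
  both are in circulation and they differ by a factor of the span: `100 ×
  (1 − P_T)` as *change over the monitored span* (the primary field) and
  the same quantity divided by the span in cycles as an *average per-year*
  change.  Neither is silently chosen; both appear in the summary object
  and the JSON writer.
* An all-zero year-1 paired sum makes the summary undefined and is an
  error, not an NA: there is no trend ratio without a baseline.
* A series spanning less than two cycles cannot pair and yields an empty
  paired set with a warning — downstream fitting then errors clearly.
* Aggregated periods (e.g. 30-day bins) count as fully logged for pairing
  when at least half their days were fully logged (bin-level threshold
  0.5, exposed); a bin with no fully logged day is absent, and bin values
  are means over fully logged days only.
* Monthly series reuse the same machinery with `C = 12` and no leap
  handling.

## Validation problem sizes

The shipped test suite runs the complete pairing combinatorics exactly;
noise-free closed forms to 12+ significant digits; 100 seeded replicates
for the no-trend summary; exact permutation enumeration at $n = 6$ (720
orderings) against 5000-draw Monte-Carlo p-values; type-I calibration with
1000 × 999-permutation replicates at length 1460; bootstrap coverage over
200 simulated data sets at 500 resamples; and the up/down-runs
permutation-mean closed form $(2n-1)/3$ at $n = 50$.  These sizes were
chosen so the whole suite completes in a few minutes while keeping
Monte-Carlo error well inside each check's tolerance.

## Known limitations

* The ratio weights sites and days by detections; a site with huge counts
  dominates a pooled regional trend.  No effort weighting is provided.
* Pairing discards all unpaired data.  With large irregular gaps the
  paired set can become small and detection-sparse, inflating the
  interval — the method fails loudly (wide CIs), but it does fail.
* The trend is *relative* (year-on-year change in detections), not an
  abundance estimate, and site representativeness is out of scope.
* The estimator is a ratio of sums, so its expectation under a no-trend
  null carries $O(1/\sum y_1)$ ratio-estimator bias — negligible at
  realistic detection totals, visible only as noise shrinks the
  denominator.
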