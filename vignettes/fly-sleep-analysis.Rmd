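---
title: "Scoring and modelling Drosophila sleep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling Drosophila sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysleepr)
```

## The operational definition of sleep

Fly sleep is scored behaviourally: any period of at least five consecutive
minutes without detectable movement counts as one sleep bout. `flysleepr`
keeps this rule deliberately pure. A sample is *immobile* if and only if
its movement value is exactly zero; everything about what counts as
"detectable" lives upstream, in the conversion from positions to movement
(`movement_from_positions()`, threshold `epsilon` in mm/s, default 1.0) or
in the beam-count nature of DAM data. `detect_sleep_bouts()` then merely
segments maximal zero-runs and applies the `min_bout` threshold (default
5 minutes).

Three boundary decisions are explicit rather than implicit:

* **Edge truncation.** An immobility run cut off by the start or end of the
  recording is scored on its observed span. A fly already immobile when
  recording starts therefore gets credit for the observed part only.
* **Missing data.** Monitor-error rows and tracking dropouts are `NA`
  samples. They break immobility runs, count as neither sleep nor wake, and
  are reported as a per-window `coverage` fraction. Silent zero-filling
  would masquerade as sleep; we never do it.
* **Bouts and phases.** Bouts are not split at lights transitions. Per-phase
  *sleep time* is computed by raster overlap with the phase window, while
  per-phase *bout count* and *mean bout duration* attribute each whole bout
  to the phase containing its onset. The two views answer different
  questions and both appear in `window_metrics()`. Mean bout duration is a
  per-fly mean, averaged across flies at the cohort level (not pooled over
  bouts), so long-sleeping flies do not dominate the group statistic.

Sleep latency is the time from lights-off to the first bout onset; a bout
already ongoing at lights-off gives latency zero, and a night with no sleep
at all is censored at the window length and flagged. Censored latencies are
excluded from group means by default and reported separately, to avoid
biasing means with flies that never slept. Waking activity is total
movement divided by minutes spent awake (counts/min for DAM, mm/min for
video), the standard control for hyperactivity confounds.

## Deprivation and rebound

Mechanical deprivation is modelled as its stimulation schedule: one 20-s
forced-wake epoch per 3-minute cycle at a random phase within the cycle,
for 12 h (`deprivation_design()`). Because every inter-stimulus gap is
shorter than 5 minutes, a fly that responds to every stimulus can never
accumulate a scorable sleep bout, which is what makes "approximately 100%
efficiency" the expected outcome of the protocol rather than an assumption.

Efficiency is `100 * (1 - deprivation-night sleep / baseline-night
sleep)`. Sleep *lost* has two conventions, both implemented because the
phrase "total sleep duration last night" is ambiguous: the default
difference form (baseline minus surviving sleep) and a strict form
(baseline night alone). Under complete deprivation the two coincide, which
is the regime the protocol produces.

The rebound curve divides the cumulative sleep regained by the sleep lost,
hourly over the recovery horizon. "Regained" is defined against the fly's
own clock-matched baseline: recovery hour *h* is compared with the baseline
hour at the same clock time in the 24 h preceding deprivation. This is the
minimal baseline assumption, works identically in LD and DD, and makes the
curve invariant to adding a constant to every hour. Percentages are never
clamped: negative rebound and overshoot are biologically meaningful.
Per-fly exclusions carry machine-readable reason codes (`baseline_zero`,
`nonpositive_loss`, `low_coverage` below 90% data) rather than being
silently dropped.

A known statistical property deserves emphasis: the per-fly percentage has
baseline-night sleep in its denominator, so flies that happened to sleep
little the night before deprivation produce extreme percentages, and
cohort means of this quantity are heavy-tailed. At n = 48 the cohort mean
is usable but noticeably noisier than the underlying sleep amounts; the
group summaries report SEMs so this is visible. We deliberately do not add
outlier trimming beyond the three documented exclusion rules.

## Free-running period

`chi_square_periodogram()` implements the Sokolove-Bushell statistic: fold
the series into K complete cycles of a candidate period P (in samples),
and compare the variance of the P column means against the total variance,

Q(P) = K N &Sigma;<sub>h</sub> (M<sub>h</sub> &minus; M)<sup>2</sup> /
&Sigma;<sub>i</sub> (x<sub>i</sub> &minus; M)<sup>2</sup>,

with Q(P) approximately chi-square on P − 1 degrees of freedom under the
no-rhythm null. The default search grid is 18–30 h in 0.1-h steps at
alpha = 0.05; non-integer periods are rounded to the nearest whole sample
for folding while the reported period stays on the grid. The best period
is the maximal supra-threshold Q; traces with no supra-threshold candidate
(including constant traces) are flagged arrhythmic rather than given a
number. The chi-square variant was chosen over Lomb-Scargle because it is
the default periodogram of the standard actogram tools this pipeline is
meant to replace, and the implementation is deliberately small enough to
swap.

## Group statistics

`compare_groups()` mirrors the standard phenotyping figure: omnibus
one-way ANOVA, then Student's two-sample t tests for each mutant against
the control (an explicit pair list can override this), with the Holm-Sidak
step-down adjustment: order the m raw p-values ascending and set
adjusted<sub>i</sub> = max<sub>j &le; i</sub> 1 − (1 −
p<sub>j</sub>)<sup>m−j+1</sup>, capped at 1. Base R's `p.adjust` offers
Holm's Bonferroni step-down but not the Sidak variant, hence the small
`holm_sidak()` implementation, which is tested against hand-evaluated
cases. Equal-variance t is the default for fidelity to common practice;
Welch is available. Stars (\*, \*\*, \*\*\*) are assigned from adjusted
p-values at 0.05/0.01/0.001, and raw p-values are always reported
alongside.

## The synthetic cohort generator

No raw recordings ship with the package; every analysis is exercised
against a generative model chosen to be the *minimal* one exhibiting the
two phenotype axes the analyses must separate — total sleep amount and
sleep homeostasis. Each fly is a per-minute two-state Markov chain with

* a circadian drive C(t) = cos(2&pi;(t − &phi;)/&tau;), peaking at
  &phi; = 18 h after lights-on (mid-night), and
* a homeostatic pressure H that charges toward 1 while awake
  (time constant &tau;<sub>w</sub> = 38 h) and discharges exponentially
  during sleep (&tau;<sub>s</sub> = 16 h),

entering sleep with probability logistic(a<sub>0</sub> + a<sub>c</sub>C +
a<sub>h</sub>H) and leaving it with probability logistic(b<sub>0</sub> −
b<sub>c</sub>C − b<sub>h</sub>H) each minute. Awake minutes emit Poisson
beam counts; asleep minutes emit zero. Waking counts carry a sharp
multiplicative bump at subjective dusk (up to 9-fold, ~±1.5 h wide), the
crepuscular activity surge characteristic of fly actograms; because the
bump only ever *adds* counts to awake minutes, it leaves the immobility
pattern — and therefore all sleep scoring — untouched, while giving
periodogram analysis the deterministic-phase landmark it locks onto in
real DAM data.

The wild-type defaults were calibrated once, against the phenomenology the
generator must emulate, and then frozen: roughly 450 min of consolidated
night sleep and 175 min of day sleep per 12-h phase under LD 12:12,
essentially complete (~100%) deprivation under the shaker schedule, and
cohort-mean recovery of lost sleep approaching 100% over the 24 h after
deprivation. Because the homeostat is slow, the chain takes days to forget
its initial pressure; `h0` therefore defaults to the stationary mean
(0.36) so that analyses are insensitive to how many baseline days precede
an intervention.

Two calibration lessons are worth recording. First, the pressure feedback
*defends* baseline sleep: lowering the sleep-drive intercept a<sub>0</sub>
is almost fully compensated by H rising until sleep is restored. Stable
low-sleep phenotypes therefore come from reducing the homeostatic gain,
not the intercept — which is how the `low_sleep` preset works
(gain × 0.7 ≈ 30% less night sleep, rebound intact), echoing the real
dissociation in which some short-sleeping mutants retain normal rebound.
Second, the `homeostat_null` preset (gain zero) needs recalibrated
intercepts (m<sub>a0</sub> = 0.41, m<sub>b0</sub> = 2.3) to sleep at all;
it then sleeps ~180 min per night and shows essentially no rebound, the
signature of a homeostasis mutant. An intermediate `homeostat_half` preset
sits between the two on the rebound axis. The compensated intercepts mean
the presets differ in more than one coordinate; early in recovery the
half-gain preset can transiently out-rebound wild type (its shallower
intercept lets it fall asleep in daytime faster), with the ordering by
total 24-h recovery restored at cohort scale.

### What the generator does and does not emulate

It reproduces: day/night sleep architecture and its consolidation,
genotype-dependent sleep amounts, homeostatic rebound with roughly full
24-h recovery in wild type and none in the null, forced-wake deprivation
with realistic shaker-driven counts, free-running rhythms at a settable
&tau; recoverable by periodogram, and fly-to-fly variability arising from
the stochastic chain. It does not emulate: bimodal siesta structure beyond
the single dusk bump, light-driven startle responses, age or sex effects,
inter-individual parameter heterogeneity (all variability is trajectory
noise), or any biochemistry of the underlying signalling. Passing tests on
synthetic cohorts therefore validate the *pipeline's arithmetic and
inferential behaviour*, not any biological claim about real recordings.

## Numerical and interface choices

* All clock arithmetic is timezone-free (UTC POSIXct); ZT0 is lights-on
  (default schedule 09:00–21:00).
* DAM files are parsed tolerantly: the 32 count columns are located as the
  trailing numeric block because field files vary in their middle columns;
  non-OK status rows become missing samples, never zeros; timestamp gaps
  are filled with explicit missing markers; malformed rows are rejected
  with their row number.
* Window metrics weight partially overlapping samples by their fractional
  overlap, which makes totals exactly additive across adjacent windows.
* Simulated experiments derive per-fly seeds deterministically from one
  master seed, so cohorts regenerate bit-identically.
* Problem sizes used in the validation suite — cohorts of 48 (the field's
  usual group size), 12-day DD recordings for period estimation, 2–4 day
  LD recordings for sleep and rebound — match the scales the analyses are
  designed for while keeping the full suite fast.

## Known limitations

The rebound percentage's heavy tail (above) is the main caveat when
comparing small cohorts. Periodogram peak selection is argmax-on-a-grid;
its resolution is the grid step and no sub-grid interpolation is
attempted. The immobility rule is binary and cannot distinguish quiet
wakefulness from sleep, a limitation inherited from the operational
definition itself.
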