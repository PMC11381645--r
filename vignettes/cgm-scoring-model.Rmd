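---
title: "A three-dimensional scoring model for CGM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-dimensional scoring model for CGM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmscore)
```

## The problem

Continuous glucose monitoring (CGM) produces a reading every 1–15
minutes, and the standard ambulatory glucose profile (AGP) metrics that
summarize it — time in range, time below/above range, coefficient of
variation — are one-dimensional: a patient can meet one target while
badly missing another, and a clinic tracking hundreds of patients has no
single quantity that says *who needs attention first and why*. This
package implements a three-dimensional scoring model that reduces a CGM
record to a hypoglycemia score, a hyperglycemia score and a variability
score — each on 0–100, higher is better — plus one *single score* and a
color segment that together identify the most alarming dimension of
glycemia for a patient or period.

## The model

### Daily indices

For each calendar day on a harmonized 15-minute grid (96 slots) three
established indices are computed:

* **LBGI / HBGI** (low / high blood glucose index). Glucose `BG` in
  mg/dL is symmetrized by `f(BG) = 1.509 ((ln BG)^1.084 − 5.381)`,
  which is zero near 112.5 mg/dL, negative below and positive above,
  with a deliberately steeper branch on the hypoglycemic side. The slot
  risk is `r = 10 f(BG)²`, attributed to the low index when `f < 0` and
  to the high index when `f > 0`; LBGI and HBGI are the day's means of
  the two attributions. Squaring makes rare deep excursions count
  heavily, which is the clinical rationale for using these rather than
  raw time-below-range: hypoglycemia is dangerous out of proportion to
  its duration.
* **GVP** (glycemic variability percentage), the excess length of the
  glucose trace over a flat trace of equal duration:
  `(L/L0 − 1)·100` with `L = Σ √(Δt² + Δg²)` (minutes, mg/dL) over
  consecutive observed slot pairs and `L0` the elapsed time they cover.
  Unlike CV%, GVP responds to the *frequency* as well as the amplitude
  of excursions.

### Normalization to dimension scores

Each index is min–max normalized to a score,
`100 (1 − (x − min)/(max − min))`, clamped to [0, 100]. The anchors
(`normalization_params()`) are: LBGI 0–8, HBGI 0–32 for adults and
0–30 for pediatric patients, GVP 20–67. The minima are the best
attainable values (LBGI/HBGI of 0; a GVP of 20% is the best level
reported for people without diabetes), so they score 100; the maxima
were calibrated as the 98th percentile of a large clinical T1D cohort,
so a score of 0 marks the most alarming ~2% of days. Because raw
indices can exceed a 98th percentile by construction, clamping is what
keeps scores inside [0, 100]. `fit_normalization()` refits the maxima
from any cohort of daily indices at a configurable percentile, with the
HBGI maximum stratified by cohort (pediatric treatment targets are
stricter).

### Period aggregation and the single score

Scores are aggregated over sliding windows of 14 calendar days (any
length is supported). A plain mean over days would average away a
dangerous minority of hypoglycemic days, while taking the worst single
day overweights them; balancing the severe excursion metrics on both
sides leads to representing the hypoglycemia dimension by the mean of
the `k = ⌈fraction · n⌉` *lowest* daily hypoglycemia scores with a
default fraction of 0.5 (7 of 14 days). The hyperglycemia and
variability dimensions are plain means. `hypo_subset_sweep()`
reproduces the subset-size exploration that motivates the default. The
single score is the minimum of the three period dimensions — a high
single score therefore certifies that *every* dimension is at least
that good — and is binned into five segments of 20 points (dark red,
red, orange, yellow, green; each interval closed on its lower bound,
green = [80, 100]).

### Availability rules

Real CGM records have gaps. Days with less than 70% of their 96 slots
observed are excluded; windows qualify when the retained days supply at
least 70% of the `14 × 96` expected slots, with excluded days counting
as fully missing (one uniform denominator keeps the rule
interpretable). Windows slide by one day. Readings outside the typical
sensor reporting range [39, 400] mg/dL are clamped at ingestion, and
all internal math is in mg/dL (18.018 mg/dL per mmol/L; the consensus
thresholds 3.9/10.0/13.9/3.0 mmol/L are converted once, exactly).

## Calibration against treatment targets

`calibrate_cgm()` labels every window by fulfillment of the consensus
CGM targets (TIR ≥ 70%, TBR ≤ 4%, TSBR ≤ 1%, TAR ≤ 25%, TSAR ≤ 5%,
CV ≤ 36%; boundaries inclusive toward fulfillment, all configurable via
`target_set()`) and asks what single-score cutoff identifies fulfilled
windows with a false positive rate of at most 2.5%: the empirical ROC
is scanned over observed scores only, and the smallest admissible score
becomes the cutoff. The AUC is the trapezoidal area under that
empirical curve (equivalently the Mann–Whitney statistic, which the
tests use as an independent oracle). Spearman correlations between the
four scores and eight AGP metrics, and second-degree least-squares
polynomials of each metric on its score (with the per-segment expected
AGP table they imply), complete the calibration outputs.

## Missing-data robustness

`robustness_experiment()` reproduces the missing-data protocol: 30-day
sets with ≥ 90% availability per day and overall are the "full data"
baselines (`select_full_sets()`); each is degraded either by keeping a
uniformly random fraction (10%–80% in steps of 10) of its observed
slots or by deleting 1–29 whole days in steps of 3, then rescored as a
single window. Reported per level: the distribution of the score
difference (degraded − true; positive = falsely improved) and the
fraction of sets whose lowest dimension is preserved.

One design choice deserves emphasis: degraded sets are rescored
*without* the daily 70% availability filter (the `min_day_availability`
argument restores it). Re-applying the filter would leave zero scorable
days at any retention at or below ~60% — the filter threshold times the
base availability — making the heavier half of the protocol degenerate,
whereas the point of the experiment is precisely to quantify what a
score computed from thin data is worth.

## The synthetic cohort generator

No clinical data ship with the package, so `simulate_cohort()`
generates T1D-like traces: a mean-reverting (Ornstein–Uhlenbeck)
baseline integrated with Euler steps on the sampling grid, plus meal
excursions (Poisson arrivals, log-normal amplitude, 30-minute linear
rise, exponential decay) and hypoglycemic dips (Gaussian-shaped drops
toward an absolute nadir level, so hypoglycemic burden is controlled by
the dip rate independently of the baseline), clamped to [39, 400]
mg/dL, with independent slot dropout plus geometric multi-slot gaps.
All randomness derives from one root seed through per-patient
substreams, so any patient can be regenerated alone.

Cohort defaults were chosen once to emulate a mixed T1D clinic
population: 50 patients × 30 days at 15-minute sampling, baseline drawn
from 110–220 mg/dL, diffusion 5–22 mg/dL/√h, three meals/day with
30–120 mg/dL amplitude and a one-hour decay half-life, dips at 0.1–4
per day reaching ≈ 55 mg/dL with a 75-minute width, 2% dropout, 38%
pediatric (the adult/pediatric split of the cohort the model was
originally calibrated on). Under these conditions the synthetic
cohort's daily-index 98th percentiles come out around 5 (LBGI), 21
(HBGI) and 85 (GVP) — the same order as the published anchors 8, 30–32
and 67 — and about 5–13% of windows fulfill all consensus targets.

What the generator does *not* emulate: circadian structure (dawn
phenomenon, meal timing), insulin-driven autocorrelation between
excursions and dips, sensor error (noise, drift, compression lows), or
informative missingness. Tests passing on this cohort therefore
demonstrate the *internal* contracts of the scoring model — monotone
responses, rank correlations, filter arithmetic, reproducibility — not
clinical validity on real traces, and cohort-dependent published
figures (AUC, accuracies, correlation magnitudes) are treated as
properties to mirror qualitatively, not numbers to reproduce.

## Numerical and design choices

* Resampling is a bin mean over left-closed 15-minute bins anchored at
  midnight — robust across 1-, 5- and 15-minute sensors; resampling an
  already-gridded series is the identity. Duplicate timestamps are
  averaged; out-of-order input is sorted, not rejected.
* GVP bridges gaps with the true elapsed time, so missing data dilutes
  rather than inflates curve length; days need ≥ 2 observed slots for
  GVP and ≥ 1 for LBGI/HBGI, otherwise the day is dropped from
  aggregation.
* Below/above-range AGP metrics use strict inequalities and TIR the
  closed complement, so TIR + TAR + TBR = 100 exactly; CV% uses the
  population SD (fixed for determinism; immaterial at n ≈ 96); GMI is
  the standard linear map `3.31 + 0.02392 · mean`.
* `k = ⌈fraction · n⌉` lets shortened windows keep at least one
  hypoglycemia-representative day; ties for the lowest dimension
  resolve hypoglycemia → hyperglycemia → variability, mirroring the
  model's emphasis on hypoglycemic risk.
* The ROC threshold scan uses observed scores only (no interpolation),
  and Spearman p-values use the exact distribution below n = 30 and the
  t approximation above.
* Scoring windows for a degraded 30-day set are taken as one 30-day
  window rather than sliding 14-day sub-windows.

## Problem sizes

The test suite and the reproduction script run everything at desk
scale: the graded cohort is 50 patients × 30 days (≈ 850 windows of 14
days), robustness uses ~5 full 30-day sets × 4 retention levels × 20
replicate degradations, and oracle-equivalence checks loop over a few
dozen random 96-slot days. A full run of the suite takes well under a
minute on one core.

## Limitations

The normalization anchors are cohort-calibrated constants; on a
population very unlike the calibration cohort the score distribution
shifts, which is why `fit_normalization()` exists. The score is a
screening statistic, not a treatment decision: the green segment is
calibrated for high specificity (few falsely reassuring scores) at the
cost of sensitivity, so a below-80 score flags a period for human
review rather than diagnosing failure. And all quantitative guarantees
verified here are guarantees on synthetic data with known generative
structure.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(seed = 101))
scores <- lapply(seq_along(co$series), function(i)
  score_cgm(co$series[[i]], cohort = co$truth$cohort[i]))
cal <- calibrate_cgm(scores)
cal$roc
plot(scores[[1]])
```
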