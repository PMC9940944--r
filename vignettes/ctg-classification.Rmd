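---
title: "Rule-based intrapartum CTG classification: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based intrapartum CTG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgtier)
```

## The problem

Cardiotocography (CTG) records the fetal heart rate (FHR) together with
uterine activity during labour. Clinicians grade the trace into ordered
risk categories using one of several published rule systems; the grade
drives decisions about expedited delivery. This package implements four
such systems as executable rules — FIGO 2015 and RCOG 2001
(normal / suspicious / pathological), NICHD 2008 (Categories I-III) and
the Parer-Ikeda five-tier colour scheme (green to red) — together with
the feature extraction they require and the diagnostic-evaluation
statistics used to compare them against a neonatal outcome (severe
acidemia, umbilical artery pH < 7.00).

All four systems consume the same small vocabulary of features: a
baseline level, minute-scale variability, accelerations, decelerations
(typed early / variable / late / prolonged and graded by severity), a
sinusoidal pattern, and whether decelerations are repetitive (accompany
more than half of the contractions). The `FeatureBundle` class is that
vocabulary made explicit: classifiers read a bundle and nothing else, so
the same rules apply to extracted signals, to pre-annotated bundles and
to synthetic ground truth.

## Signal model

A `CTGTrace` is a uniformly sampled window (default 4 Hz, the
conventional acquisition rate) of paired FHR and toco channels. Missing
signal is an explicit `NA` mask, never interpolated at load time;
`fillGaps()` linearly interpolates gaps up to a threshold (default 15 s)
and leaves longer ones missing. Non-missing FHR values outside the
physiologic guard rails 30-250 bpm are coerced to missing on load.
Windows with more than half the signal missing after gap filling are
refused — the clinical analogue of an unusable trace. Analysis uses the
trailing 30-60 minutes of a recording (`extractWindow()`), the interval
that best reflects the state at birth. Times are seconds from the window
start, with half-open event intervals.

## Feature extraction

**Baseline.** Per 10-minute segment, the baseline is the mean after
iteratively excluding excursions: starting from the segment median,
samples deviating >= 15 bpm from the provisional baseline for >= 15 s
are excluded — each excluded run padded by 25 s, so the shallow flanks
of a deceleration (the part still within 15 bpm of baseline) do not bias
the mean — and the mean is recomputed until stable (at most five
iterations). NICHD and PARER values are rounded to the nearest 5 bpm
(their stated convention); FIGO and RCOG values are reported at 0.1 bpm.
The window value is the usable-minutes-weighted modal 5-bpm band over
segments; ties break toward more minutes, then toward the lower band
(conservative toward bradycardia). A segment with under 2 usable minutes
is indeterminate.

**Variability** is the per-minute bandwidth (max minus min) of the
signal, excluding minutes that overlap detected events (padded 15 s) or
a qualifying sinusoidal episode. Excluded minutes do not interrupt a
reduced- or increased-variability episode; duration accounting runs over
the sequence of included minutes. The summary class uses each system's
bands (normal 5-25 bpm for FIGO/RCOG, 6-25 for NICHD/PARER; absent
< 2 bpm; increased > 25 bpm), and the duration rules (e.g. FIGO reduced
> 50 min, RCOG reduced 40-90 min nonreassuring / > 90 min abnormal) use
the longest episode.

**Events.** Accelerations and decelerations are threshold-crossing
excursions: a core of >= 10 s beyond baseline +/- 15 bpm, grown outward
while the signal stays beyond +/- 5 bpm, kept when >= 15 bpm deep/high
and >= 15 s long. Accelerations of 2-10 min are flagged prolonged;
>= 10 min excursions are dropped as candidate baseline shifts.

Two numerical choices matter for decelerations with flat bottoms
(U-shapes): the literal sample argmin lands anywhere on the plateau, so
the *nadir time* is reported as the midpoint of the "deep region"
(samples within `2 + 0.05 * depth` bpm of full depth — robust for
measuring the lag to the contraction peak on symmetric shapes) and
*onset-to-nadir* as the time from onset to the deep region's first
sample (robust for abruptness). With these conventions a 10-s drop reads
abrupt and a symmetric 45-s ramp reads gradual, regardless of plateau
length.

**Typing** is a partition. An event is prolonged when longer than the
system's threshold (NICHD/PARER > 2 min; FIGO > 3 min; RCOG, whose
definition is an *abrupt* decrease of >= 60 s: abrupt and >= 60 s, or
any shape beyond 3 min). Otherwise abrupt events (onset-to-nadir < 30 s)
are variable; gradual events are early when the nadir is within 20 s of
the nearest contraction peak and late when it trails by more than 20 s.
The 20-s cut makes early/late a true partition of gradual decelerations,
complementing the RCOG "nadir > 20 s after the peak" late rule. A nadir
*leading* the peak by over 20 s is kept early (an early-onset periodic
slowing). A gradual event with no contraction within 120 s is typed
variable by convention and flagged indeterminate.

**Severity** follows the five-tier grading: variables by nadir level and
duration (severe below 70 bpm for over 60 s; moderate below 70 bpm for
30-60 s or below 80 bpm for over 60 s), lates by depth (mild <= 15,
moderate 16-44, severe >= 45 bpm below baseline), prolonged by nadir
(severe < 70, moderate 70-80 bpm). The printed grading for prolonged
events is not monotone as published (moderate < 70, severe 70-80); we
adopt the monotone reading — deeper is worse — and likewise resolve the
overlapping printed clauses for severe variables. RCOG's undefined
"typical vs atypical" variables use a cut mirroring the five-tier
severity floor: atypical when >= 60 s or dipping below 70 bpm.

**Sinusoidal pattern.** A minute is sinusoidal when the dominant
spectral component of the detrended signal lies at 3-5 cycles/min and
carries more than half the oscillatory power, the half-range amplitude
is 4-16 bpm (one bpm of slack around the defining 5-15 band) and no
acceleration overlaps. Qualifying durations: FIGO > 30 min, RCOG
>= 10 min, NICHD and PARER > 20 min (NICHD states no duration; the
five-tier value is used).

**Repetitiveness**: a type is repetitive when it accompanies strictly
more than 50% of contractions (nadir within the contraction +/- 30 s).
NICHD "recurrent" is operationalised identically — NICHD 2008 defines it
the same way.

## Classifiers

FIGO and RCOG return the most severe applicable category (firing several
pathological clauses changes nothing). NICHD Category II is exactly the
complement of I and III, which is asserted property-style in the tests.

The Parer-Ikeda colour matrix ships as an editable CSV
(`inst/extdata/parer_rules.csv`, 220 cells) keyed by variability class
(moderate / minimal / absent / marked), baseline class (normal,
tachycardia, mild / moderate / severe bradycardia) and worst
deceleration (`type:severity`). The published three-column layout is
garbled in places (cells listed under two colours, bradycardia cells
missing); each reconstructed-by-inference cell defaults to the *more
severe* adjacent colour — the fail-safe direction for a clinical
screening rule — and carries a note in the CSV's `note` column.
`validateParerRules()` enforces totality and severity monotonicity at
load, and a qualifying sinusoidal pattern forces red. Marked
variability, listed only as its own yellow row, is graded as at least
yellow and otherwise follows the moderate-variability column.

## Evaluation statistics

`buildContingency()` tabulates classified case/control records per
system. Per-category diagnostics dichotomise the ordered table with the
polarity convention that reproduces the published tables: the most
normal category is a *negative* test (positive = any other category);
every other category is itself the positive test. Ratios with zero
denominators are flagged undefined, never infinite.

The ordinal AUC is the tie-corrected Mann-Whitney estimator
$\mathrm{AUC} = \frac{1}{mn}\sum_k c_k\,(C_{<k} + \tfrac12 C_k)$ over
case counts $c_k$ and control counts $C_k$ per ordered category — the
probability a random case is graded worse than a random control, ties
counting half. It is checked exactly against a brute-force all-pairs
oracle, and `rocPoints()` returns the cumulative-threshold ROC polygon
whose trapezoidal area equals it to 1e-12. Confidence intervals:
Hanley-McNeil (default; closest to common statistical-package output),
DeLong placement-value variance, or a percentile bootstrap that
resamples subjects within groups (seeded). Under a null with identical
case/control category distributions (43 + 43 subjects, proportions
14/22/7 over three categories), the bootstrap interval covered 0.5 in
93.4% of 1,000 seeded replicates — within sampling slack of nominal for
a percentile interval at this sample size.

Fleiss' kappa uses the standard marginal-chance formula and is verified
against an independent pairwise-agreement oracle and a published
14-rater worked example (kappa = 0.210); when the margins force
agreement 1, kappa is undefined and flagged rather than reported as a
number.

## The synthetic generator

`generateTrace()` renders a `traceSpec` — baseline, a band-limited noise
carrier rescaled minute-by-minute to an exact peak-to-trough amplitude
(default band 6-18 cycles/min, safely above the 3-5 cycles/min
sinusoidal band), raised-cosine contractions (default every 180 s),
piecewise-linear decelerations (symmetric triangles for gradual events,
U-shapes with 10-s or 20-s ramps for abrupt ones), trapezoid
accelerations, optional pure-sine episodes and signal-loss gaps — and
derives per-system ground-truth `FeatureBundle`s using the same shared
typing/grading rules the extractors use. The carrier is attenuated to
20% inside events, mirroring the reduced internal variability of real
decelerations and making nadir depths analytically checkable.
Generation is deterministic given the seed.

Cohorts are generated at the *category* level: `generateCohort()`
assigns counts exactly, so contingency-level statistics carry no
sampling error. This two-layer design reflects what can honestly be
emulated: the package's synthetic signals exercise the *definitions*
(shapes, thresholds, durations), not the messiness of real monitors —
no Doppler artifact, no maternal-heart-rate capture, no drifting
baselines, no expert disagreement. Passing round-trip tests therefore
demonstrates that extraction and classification implement the rules
consistently, not that the extractor matches human readers on clinical
traces.

Round-trip testing uses 50 seeded specs spanning all deceleration
types and severities, baselines from severe bradycardia to tachycardia,
variability from absent to marked, sinusoidal episodes and gapped
signals, with margins (depths >= 25 bpm, durations away from rule
boundaries) chosen so every spec is unambiguous under all four systems.
Problem sizes throughout the test suite (60-minute windows at 4 Hz,
10,000 sampled bundles over the 630-cell feature grid for monotonicity,
1,000 x 1,000 bootstrap replicates for interval coverage) keep the full
suite under a minute on a single core.

## Reproducing the published comparison

The packaged fixtures carry the source study's per-category case/control
counts (43 traces with umbilical artery pH < 7.00 vs 43 controls) plus
the printed diagnostic values and AUCs. `reproducePaper()` recomputes
every cell and compares at +/-0.15 percentage points (proportions) and
+/-0.05 (likelihood ratios). Two groups of printed values are internally
inconsistent with the printed counts and are annotated as known
discrepancies rather than matched: the five-tier blue row and NICHD
Category II row (no single polarity convention yields them), the FIGO
pathological NPV (printed 67.4%, counts give 36/57 = 63.2%) and the red
LR- (printed 0.4, counts give 0.74). Two further printed values differ
slightly from computation and are surfaced by the report: the RCOG AUC
(counts give 0.7147, printing as 0.71, vs a printed 0.72 — consistent
with a double rounding of 0.715) and the FIGO suspicious NPV (printed
46.5%; counts give 21/45 = 46.7%). Everything else reproduces to
print precision; the repro path contains no randomness and is
bit-identical across runs.

## Known limitations

* The extractor targets the visually defined features of the rule
  systems; it is not a beat-to-beat computerised CTG analysis (no
  short-term-variability indices) and does no artifact correction.
* RCOG duration clauses beyond 90 minutes can never fire inside a 30-60
  minute analysis window; they are implemented for completeness.
* The Parer-Ikeda matrix is a documented reconstruction; cells marked in
  its `note` column are inferential and deliberately severe. Users can
  edit the CSV; validation re-checks totality and monotonicity.
* The published interobserver kappas cannot be recomputed — per-rater
  assignments were never published — so `fleissKappa()` is verified on
  synthetic and textbook data instead.
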