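---
title: "Validating early warning scores on geriatric ward data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating early warning scores on geriatric ward data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gews)
```

## The problem

Early warning scores (EWS) convert a bedside set of vital-sign measurements
into a single integer that flags physiological deterioration. In frail older
inpatients, standard tools such as the National Early Warning Score (NEWS)
are thought to under-perform: age-related physiology shifts the thresholds
at which vital deviations become meaningful, producing both false alarms and
missed deterioration. The Geriatric Early Warning Score (GEWS) adapts the
NEWS framework with frailty-adjusted bands, a graded oxygen-therapy item,
agitation scored as the most severe consciousness state, and pain
(NRS/PAINAD) as an eighth scored item.

This package implements the full statistical machinery needed to validate
one such score against another on longitudinal ward data: band-table
scoring, episode construction and observation labeling, two-stage
missing-score imputation, discrimination and alert-burden metrics,
patient-clustered bootstrap and permutation inference, and a synthetic
cohort generator so that every stage is testable without patient data.

## Scoring model

A score is *data, not code*: a band table maps each parameter to a subscore
in 0--3 through an ordered list of value bands (see
`system.file("extdata", "gews.bands", package = "gews")`). The composite
`total` is the sum of subscores; `max_single` supports the "any single
parameter scoring 3" (S3) trigger rule. NEWS scores six parameters 0--3
plus a binary oxygen item worth 2 (maximum 20); GEWS scores eight items
0--3 (maximum 24). Forehead temperatures are corrected by +0.2 °C before
banding; axillary, temporal and tympanic readings are used as recorded, and
a temperature without a recorded site is conservatively left uncorrected
(with a warning).

Three numerical choices matter:

* **Printed gaps.** Published bands are printed as closed integer or
  one-decimal ranges (`12–20`, `21–24`), leaving fractional measurements
  such as 20.5 unassigned. At load time each gap is attached to the lower
  band, so the bands exactly partition the physiologic domain;
  `score_observations(strict = TRUE)` flags values that fell in a printed
  gap. Band placement is validated on load: non-overlap, domain coverage by
  exhaustive sweep, and a unimodal severity valley (subscores non-increasing
  then non-decreasing across the value axis).
* **Ambiguous published columns.** Where the GEWS table's printed column
  alignment is ambiguous (notably heart rate 76--95 vs 96--120 and systolic
  pressure 190--220), the bundled file records one positional reading; any
  correction is a one-line edit to the band file, not a code change.
* **Missing parameters.** `score_observations(missing = "keep")` leaves the
  subscore `NA` for the imputation stage; `missing = "zero"` scores it 0
  immediately, for standalone use without a longitudinal context.

Trigger rules are configuration, not policy: the defaults are NEWS ≥ 5
(with and without S3), NEWS ≥ 7, GEWS ≥ 4 S3, GEWS ≥ 5 (with and without
S3), and GEWS ≥ 8.

## Episodes and observation labels

Deterioration events are typed 1--4: unexpected death, unanticipated
intensive-care transfer, unexpected transition to palliative care (jointly
"life-threatening", Type 1--3), and urgent unexpected medical or surgical
intervention (Type 4). Before labeling, events are merged per patient: a
Type 1--3 event within 12 h after a Type 4 event absorbs it (the merged
unit keeps the Type 1--3 timestamp); at most one Type 1--3 event per
patient is retained; simultaneous events keep the most severe type.

Each hospitalization is split into at most two analysis episodes. The first
starts at emergency-department arrival. If any Type 4 event falls within
the first 72 h, the second episode starts 72 h after the *last* Type 4
event of the first episode; we compute that boundary as a fixed point, so a
Type 4 event inside the extended first episode extends it again. If no
early Type 4 event occurs, the whole stay is one episode (the split exists
only to re-admit post-Type-4 observation time to analysis).

Every observation set gets exactly one label. All windows are half-open so
each instant has a unique class, and an observation at exactly 12 h before
an event takes the more severe (event) class:

* **event**: within `[t − 12 h, t)` of the nearest upcoming outcome event.
* **neutralized** (excluded from analysis, minimizing treatment bias):
  within `[t − 24 h, t − 12 h)` of any event; after a Type 1--3 event
  through discharge; after a Type 4 event until the end of its episode; or
  within 12 h before an event type excluded from the outcome set.
* **non_event**: otherwise.

Precedence follows the clinical logic: a Type 1--3 event window overrides
post-Type-4 neutralization (the deterioration is real and upcoming), while
a Type 4 event window does not rescue observations already neutralized by
an earlier event in the same episode. In the life-threatening (Type 1--3)
analysis, Type 4 events stop anchoring event windows but keep all their
neutralization effects, including their own 12-h pre-window — a choice the
source material leaves open; we prefer it because those observations are
treatment-proximal without an analyzable outcome.

The labeler is verified against an independent exhaustive
interval-membership oracle on a hand-enumerated five-patient fixture
(`generate_worked_fixture()`) and on 1,000 random event/observation
configurations.

## Imputation

Missing values are imputed on the *subscore* scale (0 is a valid score but
not a valid vital value), in two stages. Stage 1 imputes 0 when the set is
the patient's first, when no prior value of that parameter was documented,
when more than 12 h elapsed since the previous observation set, or when the
set is neutralized (still imputed so later carry-forward chains are
well-defined; the set remains excluded downstream). Stage 2 carries the
previous observation set's completed subscore forward. Because stage-1
zeros act as chain anchors, a carried value can never bridge a gap longer
than 12 h. The 12-h gap is measured between observation *sets* by default;
`gap_basis = "parameter"` measures it against the last measurement of that
specific parameter, exposed for sensitivity analysis. Carrying a value
measured in the emergency department onto the ward is allowed — no rule
forbids it.

## Metrics

The unit of analysis is a single observation set; neutralized sets are
excluded before any metric. Per trigger rule we report the 2×2 counts,
accuracy, sensitivity, specificity, PPV, NPV, and three burden metrics:

* NNE (number-needed-to-evaluate) = alerts per true-positive alert = 1/PPV,
* ROA (rate-of-alerts) = 100 × alerts / patient-days,
* AOER (alerted-outcome-event-rate) = 100 × TP / patient-days,

which satisfy AOER = PPV × ROA and NNE = ROA/AOER; these identities are
asserted to 10⁻¹² on every computed report. Metrics with a zero denominator
are reported as `NA`, never silently 0. `ward_rate()` rescales
per-100-patient-day rates to expected counts on a ward (a fully occupied
24-bed ward accrues 24 patient-days per 24 h, a factor of 0.24).

The **patient-day denominator** is not uniquely defined by the source
material. The default is *analyzed time*: the stay minus the union of
neutralized intervals, mirroring how observation sets are retained;
`patient_days_method = "stay"` uses the full admission-to-discharge time.

AUROC uses the rank (Mann–Whitney) formulation with half credit for ties,
which equals the trapezoidal area under the empirical ROC curve; it is
tested against brute-force pairwise concordance and against an independent
ROC implementation. The PR-AUC is non-interpolated average precision over
descending score thresholds: with integer scores and rare events, linear
interpolation in PR space is biased upward, and average precision reduces
exactly to the prevalence when all scores are equal.

## Inference

Confidence intervals use a patient-clustered bootstrap percentile approach:
patients are resampled with replacement and all of a patient's observation
sets travel together, respecting within-patient correlation
(defaults: 10,000 resamples). A statistic undefined in more than half of
the resamples is reported as a failure rather than summarized. Score
comparisons use a paired Monte Carlo permutation test (default 9,999
permutations): under the null the two scores' columns are exchangeable, and
the permutation unit is the patient cluster, consistent with the bootstrap
(per-observation swapping is available for sensitivity analysis). The
two-sided p-value uses add-one smoothing and is never exactly 0. One seed
drives independent named streams for bootstrap, permutation and simulation,
so enabling one procedure never perturbs another; fixed seeds reproduce
results bit for bit.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` emulates
the cohort structure the analysis assumes: 511 patients by default; length
of stay log-normal with median 11 d (the dispersion 0.565 was chosen once
to split the asymmetric 7--15 d interquartile target on the log scale,
giving quartiles near 7.5 and 16.1 d); Type 1--3 events as a Poisson
process at 0.005 per patient-day; Type 4 events at ~0.6 per patient with an
exponentially declining hazard (mean 24 h after admission), reflecting
admission-proximal interventions; observations at ED arrival, 2 h later,
ward admission, and two jittered ward shifts per day; per-patient vital
baselines centered in both scores' 0-bands with AR(1) within-patient noise;
and per-parameter missingness that is completely at random, with pain
recording markedly worse (40%) outside one of the three simulated centers.

Deterioration is a linear ramp over the final 12 h before each event
(matching the event-window horizon). The `"gews"` profile shifts parameters
into bands GEWS scores but NEWS largely does not (heart rate toward ~100,
temperature toward ~37.9 °C, systolic pressure toward ~105 mmHg, pain
toward 8, agitation); the `"news"` profile does the converse (desaturation
toward ~91%, respiration toward ~23/min, voice-responsiveness);
`"symmetric"` applies half of each, and `effect_size = 0` removes the
signal, under which both scores discriminate at chance — the pipeline's
negative control.

What the generator does **not** emulate: treatment effects on post-event
vitals (post-event sets are neutralized anyway), mechanistic physiology,
informative missingness, measurement error structure beyond AR(1) noise,
and secular or center trends in vitals. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers planted signal under the
assumed structure — not that either score performs at any particular level
on real patients.

## Problem sizes used in the test suite

The shipped tests run the statistical checks at sizes chosen to balance
Monte-Carlo precision against runtime on one CPU: bootstrap coverage for a
clustered PPV over 200 replicates at 1,000 resamples (50 clusters of 15
sets, population PPV exactly 0.5 by logit symmetry); permutation type-I
error over 200 replicates at 999 permutations; AUROC oracle equivalence on
100 random datasets of up to 200 sets; the labeling oracle on 1,000 random
configurations; and parameter recovery on 50 replicate cohorts of 500
patients with 999 permutations each. The acceptance script validates one
default 511-patient cohort end to end.

## Known limitations

* Band tables reconstruct printed ranges; genuinely ambiguous cells are
  resolved positionally and should be edited in the band files if better
  information becomes available.
* The episode rules support at most two episodes per stay; a cohort with
  many late Type 4 events would leave long neutralized tails.
* Analyzed-time patient-days are a continuous-time analogue of the
  set-level exclusion rule; the two can differ slightly when observation
  schedules are sparse.
* The generator's Type 4 intensity (~0.6/patient, 24-h decay) is loosely
  constrained and recorded as an assumption; it is configuration, not a
  finding.
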