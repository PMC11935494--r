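---
title: "Methods: dd-cfDNA surveillance analysis for single lung transplant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dd-cfDNA surveillance analysis for single lung transplant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sltcfdna)
library(dplyr)
```

## The problem

Donor-derived cell-free DNA (dd-cfDNA) is a plasma biomarker of allograft
injury: DNA shed by the transplanted organ, reported as a percentage of total
circulating cell-free DNA. After lung transplantation it is used for
noninvasive rejection surveillance in place of protocol transbronchial
biopsies, with a positivity threshold of 1.0% validated in double-lung
recipients. Single lung transplant (SLT) recipients carry roughly half the
donor lung mass, so their raw fractions are doubled before the same threshold
is applied — `correct_for_slt()` is that pure 2× function, and
`classify_threshold()` applies the inclusive comparison (a corrected fraction
of exactly 1.0% is positive).

Two conventions run through the whole package:

* **Fractions are percentages everywhere.** 0.46 means 0.46%. No 0–1
  rescaling appears on any public surface, which removes a silent ×100 bug
  class.
* **Dates are ISO-8601 calendar dates.** All windows are whole-day
  differences; no time-of-day arithmetic.

## Cohort assignment

Each blood draw is matched against the patient's clinical events
(`assign_cohorts()`); `assignment_policy()` holds the windows. The rules, in
precedence order:

1. **Patient-level exclusion** — a flagged patient (e.g. active malignancy)
   contributes no analyzed samples.
2. **Post-event exclusion** — an acute event (biopsy, histology-documented
   ACR/AMR, infection, treatment start) *strictly before* the draw and within
   42 days excludes it (`post_biopsy` for biopsies, `post_treatment_window`
   otherwise), because surgical trauma and treatment both perturb dd-cfDNA.
3. **Suspected-AR exclusion** — a clinically suspected rejection without
   histologic confirmation in the ±42-day window excludes the draw rather
   than contaminating either the AR or STABLE cohort.
4. **Diagnostic association** — otherwise the draw joins AR
   (histology-confirmed ACR grade A1–A4 or unspecified, or treated AMR),
   INFXN (treated infection), CLAD, or OTHER (other graft injury) if a
   qualifying event lies within ±42 days; else STABLE.

Three design points deserve justification:

* **Exclusion look-back is half-open.** `event < draw ≤ event + 42 d`
  excludes; an event *on or after* the draw date associates. This is the only
  reading under which an infection cohort can exist at all — every infection
  draw would otherwise be excluded by its own defining event — and it
  reflects the biology: dd-cfDNA elevations precede clinical detection of
  rejection by weeks, so a draw shortly *before* a confirmed event is a true
  positive, while a draw shortly *after* an event mostly measures treatment
  and procedure effects.
* **CLAD is persistent.** Chronic lung allograft dysfunction is a chronic
  diagnosis by ISHLT criteria, so `clad_onset` marks a state: every later
  draw of that patient is CLAD unless a higher-precedence rule fires. It is
  never exclusionary.
* **Precedence AR > INFXN > CLAD > OTHER.** When several qualifying events
  fall in one window the draw is labelled by the predominant-status order
  with rejection (the study focus) first; such draws are flagged `ambiguous`
  and listed in the assignment report rather than resolved silently. The
  biopsy washout shares the 42-day length of the other exclusions because no
  separate washout is established; it is configurable.

The report attached to the labels enforces the accounting identity on every
run: analyzed + excluded = total, and per-reason counts sum to the excluded
count.

## The synthetic cohort generator

No patient-level dd-cfDNA dataset is publicly deposited, so the package
ships a generator (`simulate_cohort()`) that emulates the published
multicenter SLT surveillance cohort and is itself first-class, tested code.
Its defaults *are* the study conditions: 103 patients (102 analyzed + 1
excluded), 257 draws — 137 STABLE, 25 AR (ACR grades A1/A2/A3/A4/unspecified
= 8/5/0/1/7, plus 4 treated AMR), 41 INFXN, 7 CLAD, 12 OTHER — 30 draws
excluded in the post-treatment window (3 of them the excluded patient's), 5
excluded as suspected-unconfirmed AR, and laterality left/right/unknown at
0.529/0.441/0.030 (the published 52.9/44.1/2.9 sum to 99.9%, so the rounding
residual sits on `unknown`).

**Fractions.** Each cohort's corrected fraction is a two-parameter lognormal
fitted to the printed median and IQR by `calibrate_lognormal()`:
`meanlog = ln(median)` and `sdlog = (ln q75 − ln q25) / (2 z₀.₇₅)` with
`z₀.₇₅ = 0.6744898`. The fit preserves the median exactly and the log-scale
IQR width exactly; printed quartile *asymmetry* about the median is
sacrificed — two constraints, two parameters. With the default calibration
the analytic AR-vs-STABLE AUROC is
`Φ((ln 1.80 − ln 0.46)/√(0.9122² + 0.9496²)) = Φ(1.036) ≈ 0.850`, which is
the yardstick the performance estimator is checked against.

**Draw schedules.** Days post-transplant are lognormals calibrated the same
way to the printed per-cohort medians/IQRs (STABLE 230 d (130–334), AR 456
(153–570), INFXN 264 (129–503), CLAD 720 (419.5–1617)); OTHER and the
planted exclusions use the all-cohort 233 (96–489) because no per-cohort
value is printed for them.

**Event planting.** Diagnostic events are placed 0–42 days *after* their
draw (association without triggering the look-back); treatment-window
exclusions get a `treatment_start` 1–42 days *before* the draw; suspected-AR
exclusions get an unconfirmed `suspected_ar`. Within a patient, draws are
spaced ≥100 days apart whenever either draw carries events — a ±42-day
window then cannot leak into a neighbouring draw's window — while two
event-free STABLE draws may sit as close as 30 days, so the 90-day
independence subsampling below has genuine work on default data. CLAD draws
are always a patient's last, with one onset event before the first of them.
These spacing rules are what make the keystone property hold: on every seed,
`assign_cohorts()` recovers the generator's ground-truth labels exactly.

**What the generator does not emulate** — and therefore what passing tests do
not establish about real data: within-patient correlation of dd-cfDNA (draws
are independent given the cohort), biomarker kinetics and treatment-response
decay, co-occurring conditions in one window (each draw has one planted
condition), demographic covariates, and any departure of the true fraction
distributions from lognormality. The published specificity (84.6%) sits
~5 points above the lognormal idealization (79%), a visible instance of that
last gap.

## Group statistics

Summaries are medians with IQRs; quantiles use linear interpolation between
order statistics (type 7), fixed and documented because the source tables do
not name a rule. Cohort comparisons are two-sided Mann-Whitney U tests
against STABLE (`mann_whitney_two_sided()`, delegating to
`stats::wilcox.test`): exact null distribution when both groups have ≤20
tie-free observations — chosen so the smallest cohort (CLAD, n = 7) gets
exact p-values — otherwise the normal approximation with tie and continuity
corrections. Multiplicity is controlled per table with Benjamini-Hochberg
(`bh_adjust()`, via `stats::p.adjust`): the cohort table, the laterality
table and the draw-time table are each their own FDR family. The published
laterality family is reproduced exactly (all six adjusted p-values equal
0.8208); the published cohort-table CLAD adjustment (0.0129 → 0.0155) is
*not* consistent with a four-comparison BH family, which leaves 0.0129
unchanged — it matches rank 5 of a six-test family that is never enumerated —
so this package documents the discrepancy and keeps the per-table family.

One caution surfaced during testing: BH adjustment is **not** idempotent on
its own output (p = (0.05, 0.9) adjusts to (0.1, 0.9), which re-adjusts to
(0.2, 0.9)). The test suite asserts the properties that do hold — agreement
with an independent step-up oracle, monotonicity in rank order, never
decreasing any p, permutation equivariance, capping at 1.

`fit_time_trend()` is ordinary least squares of the stable-cohort fraction on
days post-transplant with the slope's two-sided t-test; an exactly flat
response reports slope 0, R² = 0 rather than 0/0. Under the generator's null
(no planted trend) the R² stays below 0.05 in ≥95% of seeds and the slope
p-values are uniform, consistent with the published R² = 0.00268 (p = 0.538).

## Diagnostic performance estimation

Repeated draws from one patient are not independent, and a naive pooled
confusion table would overweight heavily-sampled patients. The estimator
(`estimate_performance()`) handles clustering by **subsampling to
independence, then bootstrapping**, jointly repeated for 10,000 iterations:

1. *Subsample:* within each patient, shuffle the AR/STABLE draws and greedily
   keep each one compatible with all already kept — compatible meaning
   **more than 90 days apart or differently labelled**. The subset is
   redrawn every iteration, so subset-selection variance propagates into the
   CI (a `redraw_subset_each_iteration = FALSE` switch fixes one subset for
   the bootstrap-only reading). Patients whose draws are already pairwise
   compatible are detected once and passed through, which is what makes
   10,000 iterations take seconds.
2. *Bootstrap:* resample the pooled subset with replacement at its own size.
3. *Measure:* sensitivity and specificity at the (inclusive) threshold; PPV
   and NPV by Bayes' rule at the **fixed study prevalence**; likelihood
   ratios (`+LR = sens/(1 − spec)`, perfect specificity flagged as `Inf`, not
   an error); and the empirical AUROC as the probability a random AR draw
   exceeds a random STABLE draw, ties counted ½, computed by midranks.

Degenerate bootstrap draws in which a class vanishes are rejected, redrawn
and counted — all 10,000 iterations stay well-defined. Points and 95% CIs
are the median and 2.5th/97.5th percentiles per metric; a median ROC curve
is assembled pointwise on a 2%-step false-positive-rate grid. Percentile
intervals are known to under-cover slightly at these cohort sizes; the test
suite accepts 90–99% coverage for the sensitivity interval over replicated
known-truth cohorts.

The study prevalence (`study_prevalence()`) is rejection draws over the
draws surviving the post-treatment-window exclusion — suspected-AR
exclusions remain in the denominator, reproducing the published
25/227 = 11.01% — and is computed once from the full labelled dataset, never
re-estimated per bootstrap draw, so the predictive values stay anchored to
the cohort's prevalence. The denominator policy is exposed as an argument.

Two published figures are deliberately *not* reproduced by the same
arithmetic: the printed +LR (5.02) and PPV/NPV are bootstrap medians, which
differ from point arithmetic on the printed sensitivity/specificity by under
1% (e.g. 0.7778/(1 − 0.8462) = 5.06); and the printed sensitivity 77.78%
equals 14/18 exactly, suggesting a pooled confusion table, while this
package reports the iteration median — both are computable here.

## Numerical and testing choices

* Randomness: every stochastic entry point (`simulate_cohort()`,
  `estimate_performance()`, `run_pipeline()`) requires an integer seed and is
  bit-reproducible given it; the pipeline derives stage seeds from the master
  seed by fixed offsets.
* Problem sizes in the test suite are the study's own: 257-sample cohorts,
  10,000 estimator iterations for the headline check, 10,000 draws for
  calibration checks, 10,000 null pairs for the Mann-Whitney type-I-error
  check (observed level 0.05 ± 0.01 at n = 20 per group). Because a single
  25-vs-137 cohort carries roughly 4 percentage points of Monte-Carlo noise
  on the operating point, the operating-point recovery check averages three
  replicate cohorts rather than widening its bands.
* The empirical AUROC is verified against an exhaustive pair-enumeration
  oracle on 1,000 small instances and against an established ROC
  implementation (pROC) to 1e-12.
* CSV round-trips are exact for fractions printed with ≤4 decimals (the
  generator rounds raw fractions to 4 decimals for this reason).

## Limitations

The generator's independence-within-cohort assumption means the clustering
the estimator exists to handle is present only through the 30-day STABLE
draw spacing, which is milder than real repeated-measures correlation; real
within-patient kinetics could widen the true CIs further. Quartile asymmetry
of the published distributions is not reproduced. Event histories arrive
pre-abstracted — no inference from free text, spirometry or donor-specific
antibodies is attempted — and co-occurring conditions are resolved by fixed
precedence rather than clinical adjudication.
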