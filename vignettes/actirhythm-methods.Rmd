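---
title: "Methods: physical activity and circadian rhythm analysis of minute-epoch actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physical activity and circadian rhythm analysis of minute-epoch actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

`actirhythm` analyses minute-epoch (60-second) vector-magnitude activity
counts from wrist-worn accelerometers in clinical cohorts — the motivating
application is distinguishing relapsing-remitting from progressive
multiple sclerosis (RRMS/PMS) — and ships a synthetic cohort generator so
every stage is testable without participant data. This vignette explains
the models, the tunable parameters, and the design decisions.

## Preprocessing rules

Three rules gate the data, applied in order by `preprocessSeries()`:

1. **Nonwear**: every maximal run of zero counts lasting at least 90
   minutes is flagged nonwear. Runs are found on the day-concatenated
   series, so an episode straddling midnight is detected even when
   neither within-day fragment reaches 90 minutes (the rule's wording is
   about intervals, not days, and a device removed at 23:15 should not
   escape detection). Missing observations break runs: absence of data is
   not evidence of zero movement.
2. **Valid day**: at least 1296 wear minutes (90% of 1440).
3. **Inclusion**: at least 3 valid days per subject; others are excluded
   with a logged reason, mirroring the accounting a cohort study reports.

Daylight-saving transitions are resolved by `resolveDst()`: a repeated
(fall-back) hour is replaced by the minute-wise average of its two
observed copies; a skipped (spring-forward) hour is imputed minute-wise
from the mean of the same minute of day over the subject's other valid
days. Imputed minutes count as wear — the point of imputation is to
restore a complete day, and whether the wear-time denominator includes
imputed minutes is otherwise undefined; we state our choice here. In the
synthetic representation every day carries a full 1440-slot grid with the
fall-back duplicate stored alongside, so the "short final day" a fixed
recording window would produce does not arise.

## Intensity classes and calibration

A minute is **nonactive** when its count is at most 2000, **MVPA** when
above 6750, and **LIPA** between — the reference cut points, used by
default. `calibrateCutPoints()` can re-derive cohort-specific values by
exhaustive grid search (nonactive bound 500–4000, MVPA bound 4000–10000,
step 250), maximizing concordance between accelerometry-estimated
activity and the cohort's IPAQ self-report. The concordance statistic is
the average of a Spearman correlation (MVPA min/day vs IPAQ MET-min) and
a linear-weighted kappa between tertiles of each: the self-report has a
continuous and an ordinal face, and the average respects both. Ties break
toward the reference pair, then toward smaller thresholds, so results are
reproducible. Because the statistic summarizes activity above the MVPA
bound, the nonactive bound is only weakly identified by calibration —
another reason the fixed reference pair is the default.

## Physical-activity metrics

Per valid day over wear minutes: TAC (total activity counts), TLAC
(`sum(log(1 + count))` — the log transform is applied per minute, which
handles zeros and is the standard convention for epoch counts), minutes
per intensity class, and TAC within the twelve 2-hour bins. Fragmentation
dichotomizes minutes into active (count > 2000, the same bound as the
nonactive class, used consistently) versus sedentary:

- ASTP = active-to-sedentary transitions / active minutes,
- SATP = sedentary-to-active transitions / sedentary minutes.

Transitions are only counted between adjacent wear minutes: nonwear gaps
break bouts without fabricating transitions, and the final bout of a
sequence is censored (contributes minutes, no transition) rather than
inventing a transition at midnight. Daily metrics are averaged over valid
days; composition ratios (MVPA/LIPA etc.) are formed from the averaged
minutes rather than averaged per-day ratios, which keeps them defined on
days with zero denominators. Note a finite-chain property of the ratio
estimator: on a single day with ~300 active minutes the expected ASTP
deviates from the generating transition probability by order 1e-3;
estimating on a subject's pooled multi-day sequence (what
`fragmentation()` does given the concatenated series, and what the
parameter-recovery harness uses) reduces this 14-fold at two weeks of
wear.

## Circadian metrics

From the mean diurnal profile (minute-of-day average over valid days):

- **M10 / L5**: the maximal 600-minute and minimal 300-minute circular
  window means, with their clock-time midpoints. Windows may wrap
  midnight — the least-active 5 hours usually do. Ties resolve to the
  earliest window start.
- **RA** = (M10 − L5)/(M10 + L5); **DARE** = proportion of the 24-h
  profile total inside a daytime window, default 08:00–20:00
  (configurable; any reported DARE value is window-dependent).
- **Cosinor**: least squares on `x(t) = M + a·cos(ωt) + b·sin(ωt)`,
  ω = 2π/24 h, fitted on minute-level data pooled over valid days (the
  standard single-subject practice; fitting the averaged profile instead
  changes only the residual weighting, and the profile-based option is
  retained for sensitivity work). Amplitude is √(a² + b²) and acrophase
  `atan2(b, a)/ω mod 24` — the clock time of the fitted peak. A constant
  series gets amplitude 0 and missing acrophase.
- **IV / IS** on concatenated hourly means over valid days (hourly bins,
  the convention consistent with reported magnitudes): IV is the
  normalized mean-squared successive difference (→ 2 for white noise,
  ≈ 2(1 − cos(2π/24)) ≈ 0.068 for a pure 24-h cosine), IS the fraction
  of variance carried by the hour-of-day means (1 for identical days).

All landmark metrics default to the raw count scale: reported magnitudes
of M10 (thousands of counts) are count-scale even where such metrics are
described as log-acceleration summaries elsewhere; a `logScale` flag
computes them on `log(1 + count)` instead.

## Functional PCA

Subject profiles are binned to 10-minute resolution (144 points) —
stabilizing the covariance at a few hundred subjects without moving
landmark timing — centered, and decomposed by SVD; eigenvalues are those
of the between-subject sample covariance. Five components are retained by
default. Signs of principal components are arbitrary, so
`orientComponents()` fixes each eigenfunction to have positive integral
(or, when the integral is near zero, positive value at its largest-
magnitude point) and flips scores consistently; orientation is idempotent
and leaves reconstructions unchanged. No penalized smoothing is applied
by default: at 10-minute binning with hundreds of subjects the raw
covariance is already stable, and smoothing would add a tuning parameter
the analysis does not need.

## JIVE

The PA block (volume, intensity minutes, composition ratios,
fragmentation, 2-hour TAC bins) and the CR block (M10/L5 and timings, RA,
DARE, IV, IS, cosinor parameters, fPC scores 1–5) are z-scored per
feature, and each block is scaled to unit total variation so the block
with more features does not dominate (the standard JIVE convention).
Acrophase enters as (sin, cos) of its angle to avoid the 0/24
discontinuity; a flag restores raw hours. The decomposition
`X_k = J_k + A_k + E_k` is estimated by alternating truncated SVDs: the
joint part from the stacked blocks, each individual part from its block's
residual projected off the joint subject-score space, iterated to a
1e-8 change in total squared residual (500 iterations by default; the
pipeline allows 5000 because tiny cohorts with ranks near the subject
count converge slowly). Joint parts of both blocks share one row space
exactly; individual row spaces are orthogonal to it by construction.

Default ranks are 1 joint, 4 PA-individual, 3 CR-individual — the model
shape used in the motivating analysis — with a principled alternative in
`selectJiveRanks()`: sequential permutation tests that grow each rank
while the observed singular value exceeds the 95th percentile of its
permutation null (subject order permuted within one block for the joint
rank, destroying cross-block alignment; entries permuted within feature
rows for individual ranks, destroying low-rank structure). Exported
scores are standardized to unit SD and sign-oriented by the same rule as
the fPCA components.

## Association models

Descriptive comparisons use Welch's t test (a robust default where only
"t tests" is specified; the pooled-variance test is a flag away) between
the combined RRMS group and PMS, and Pearson chi-squared for categorical
covariates. Per-metric logistic regressions adjust for age, sex and BMI;
TAC and TLAC (including the 2-hour bins) are divided by their sample SD
before entry, other metrics enter natively. Confidence intervals are Wald
(the choice is stated since profile-likelihood would also be defensible);
the type-I error of this contrast is verified by simulation to sit at the
nominal 5% at n = 250. No multiplicity correction is applied to match the
per-metric presentation, but a Benjamini–Hochberg column is emitted
alongside. The M10-window sensitivity analysis recomputes the PA metrics
with wear restricted to each subject's most active 10 hours, removing
sleep-timing differences from the comparison.

## The synthetic cohort generator

`simulateCohort()` emulates a three-group cohort (RRMS-Stable,
RRMS-Suspected progression, PMS; 85 subjects per group and 14 days by
default). Within a subject, a two-state Markov chain runs minute by
minute: the active-to-sedentary probability is constant (0.27 / 0.26 /
0.30 by group — the reported group-mean ASTP values — with
sedentary-to-active 0.09 throughout), and the sedentary-to-active
probability is modulated so that active-state occupancy follows a
logistic transform of a 24-hour cosinor curve (group acrophases 14.56 /
14.61 / 14.76 h), attenuated in a 23:00–07:00 sleep window and calibrated
so the daily mean occupancy equals the chain's equilibrium — this keeps
the empirical SATP/ASTP at their generating values while coupling
fragmentation and rhythm, the interdependence the JIVE analysis presumes.
Active-minute counts are the nonactive cut plus a lognormal excess (heavy
right tail, as count data show); sedentary counts stay below the cut, so
generating states coincide with the analysis dichotomy. Group activity
levels are set so cohort means land near the reported scales (TAC ≈ 2.1 /
2.2 / 1.9 million counts, MVPA ≈ 60 / 62 / 47 min/day).

Between-subject heterogeneity is explicit: logit-scale perturbations of
the transition probabilities (SD 0.25 → ASTP spread ≈ 0.05), a log-scale
multiplier on the active-count level (SD 0.25 → TAC spread ≈ 4.5e5), a
shared log-scale multiplier on MESOR and amplitude (SD 0.2; shared so
amplitude never exceeds MESOR), and acrophase jitter (SD 1.5 h). These
match the reported group SDs and are what makes group contrasts behave
like a real cohort rather than separating perfectly.

IPAQ summaries are derived from each subject's true MVPA and LIPA minutes
(4 and 2.5 METs, scaled to a week) with multiplicative lognormal
reporting noise (SD 0.4 on the log scale), then binned at 600 and 3000
MET-min/week into low/moderate/high. Nonwear episodes are all-zero runs
of at least 90 minutes (rate 0.15/day) so they are detectable by the
nonwear rule; missingness (e.g. DST-skipped hours) is encoded as `NA`,
never zero. Everything is deterministic given the seed.

**What the generator does not emulate:** day-to-day behavioural
variation beyond the chain's own noise (synthetic interdaily stability
runs ≈ 0.86 versus ≈ 0.26 in real cohorts), weekday/weekend structure,
device noise, postural artefacts, and any real covariate–activity
confounding beyond the group means. Passing tests on synthetic cohorts
therefore validates the estimators and the pipeline plumbing, not
field behaviour of the device.

Two validation-specific generators bypass the cohort model:
`simulateCosinorSubject()` draws the pure additive cosinor model (used to
verify the cosinor estimator under its own model; values may be negative
since the additive model has no floor, which is exactly why the cohort
generator drives a probability curve instead — the reported amplitude can
exceed the reported MESOR, impossible for a nonnegative mean curve), and
`simulateBinaryStates()` draws a stationary two-state chain for
fragmentation recovery.

## Numerical choices and edge cases

- M10/L5 ties: earliest window start wins.
- Zero-variance hourly series: IV and IS are reported missing.
- A subject with no valid imputation source for a DST hour keeps the
  missing hour and is flagged rather than silently zero-filled.
- Zero-activity profiles make RA and DARE undefined (missing / error).
- Degenerate covariates (a single observed level) are dropped from a
  logistic model rather than crashing it; perfect separation is flagged
  in the output.
- Problem sizes in the validation suite — 85 subjects × 14 days for
  parameter recovery, n = 250 for the JIVE construction and type-I
  simulation (800 replicates) — were chosen as the smallest sizes at
  which Monte-Carlo error is comfortably below the tolerances tested.

## Known limitations

- The calibration statistic identifies the MVPA bound well and the
  nonactive bound only via the tie rule; a richer concordance target
  (e.g. including LIPA-sensitive summaries) would identify both.
- JIVE rank selection by permutation is approximate for the individual
  ranks (the joint estimate is plugged in); it recovers constructed
  structure reliably but inherits the usual sequential-testing caveats.
- Sleep staging, bout-duration distributions and multilevel (day-within-
  subject) functional PCA are out of scope.
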